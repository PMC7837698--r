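#' Per-cluster mean expression profiles over time
#'
#' For every cluster and condition, the gene x timepoint matrix of mean
#' TP10K expression — the unit on which phase statistics and cluster
#' similarity operate.
#'
#' @param expr genes x cells TP10K matrix.
#' @param meta per-cell metadata with `cell`, `timepoint_h`, `condition`.
#' @param clusters named cluster vector or data.frame with `cell`, `cluster`.
#' @return object of class `cluster_profiles`: a list per cluster with one
#'   genes x timepoints matrix per condition and `n_cells`; attributes
#'   `timepoints`, `conditions`.
#' @export
cluster_profiles <- function(expr, meta, clusters) {
  labs <- if (is.data.frame(clusters))
    setNames(clusters$cluster, clusters$cell) else clusters
  meta <- meta[match(colnames(expr), meta$cell), , drop = FALSE]
  ut <- sort(unique(meta$timepoint_h))
  conds <- sort(unique(meta$condition))
  out <- list()
  for (cl in sort(unique(labs[colnames(expr)]))) {
    ent <- list(n_cells = 0L)
    for (cond in conds) {
      sel <- !is.na(labs[colnames(expr)]) & labs[colnames(expr)] == cl &
             meta$condition == cond
      if (!any(sel)) next
      hrs <- meta$timepoint_h[sel]
      X <- expr[, sel, drop = FALSE]
      prof <- vapply(ut, function(t) {
        idx <- which(hrs == t)
        if (!length(idx)) return(rep(NA_real_, nrow(X)))
        Matrix::rowMeans(X[, idx, drop = FALSE])
      }, numeric(nrow(X)))
      dimnames(prof) <- list(rownames(expr), ut)
      ent[[cond]] <- prof
      ent$n_cells <- ent$n_cells + sum(sel)
    }
    out[[cl]] <- ent
  }
  structure(out, timepoints = ut, conditions = conds,
            class = "cluster_profiles")
}

#' Marker rule
#'
#' One row of the identity rule table: an anatomical label awarded when all
#' `present` genes are positive, all `absent` genes are negative, and (if
#' given) at least one `present_any` gene is positive.  `special` marks the
#' two non-marker rules: `"antiphase_dd"` (identity awarded when the clock
#' gene's DD phase is ~12 h from its LD phase) and `"correlation_fallback"`
#' (identity assigned from the most similar annotated cluster).
#'
#' @param identity anatomical label.
#' @param present,absent,present_any gene sets (disjoint `present`/`absent`).
#' @param special `NA`, `"antiphase_dd"` or `"correlation_fallback"`.
#' @param priority unique integer; lower fires first.
#' @return object of class `marker_rule`.
#' @export
marker_rule <- function(identity, present = character(),
                        absent = character(), present_any = character(),
                        special = NA_character_, priority) {
  if (length(intersect(present, absent)))
    stop("present and absent overlap for ", identity)
  if (!is.na(special) &&
      !special %in% c("antiphase_dd", "correlation_fallback"))
    stop("unknown special flag: ", special)
  structure(list(identity = identity, present = present, absent = absent,
                 present_any = present_any, special = special,
                 priority = as.integer(priority)),
            class = "marker_rule")
}

#' Default clock-neuron identity rules
#'
#' Encodes the marker logic of the Drosophila clock-neuron classes:
#' Pdf+/sNPF+ s-LNv, Pdf+/sNPF- l-LNv, ITP+ LN_ITP, Trissin+ LNd_Trissin,
#' AstC-R2+/NPF+ LNd_NPF, AstC-R2+/NPF- LNd, CCHa1+ DN1a, AstA+/AstC+ LPN,
#' tim antiphase in DD DN2, CNMa+ with gl or Dh31 DN1p_CNMa, gl+ (or
#' Dh31+/CNMa+) DN1p, and a correlation fallback that labels the remaining
#' marker-poor clusters DN3.  The table is plain data the user can edit.
#'
#' @return list of [marker_rule()]s in priority order.
#' @export
default_clock_rules <- function() {
  list(
    marker_rule("LPN", present = c("AstA", "AstC"), priority = 1),
    marker_rule("s-LNv", present = c("Pdf", "sNPF"), priority = 2),
    marker_rule("l-LNv", present = "Pdf", absent = "sNPF", priority = 3),
    marker_rule("LN_ITP", present = "ITP", priority = 4),
    marker_rule("LNd_Trissin", present = "Trissin", priority = 5),
    marker_rule("LNd_NPF", present = c("AstC-R2", "NPF"), priority = 6),
    marker_rule("LNd", present = "AstC-R2", absent = "NPF", priority = 7),
    marker_rule("DN1a", present = "CCHa1", priority = 8),
    marker_rule("DN2", special = "antiphase_dd", priority = 9),
    marker_rule("DN1p_CNMa", present = "CNMa",
                present_any = c("gl", "Dh31"), priority = 10),
    marker_rule("DN1p", present = "gl", priority = 11),
    marker_rule("DN1p", present = c("Dh31", "CNMa"), priority = 12),
    marker_rule("DN3", special = "correlation_fallback", priority = 13)
  )
}

#' Marker positivity
#'
#' Operationalizes "expressed in" statements: a cluster is positive for a
#' gene when at least `pct_min` of its cells express it and its mean
#' expression reaches `mean_min` TP10K (both boundaries inclusive).
#'
#' @param dot_row one row of [dot_stats()] output (or a list with `pct` and
#'   `mean_tp10k`).
#' @param pct_min,mean_min thresholds (defaults 0.5 and 1.0 TP10K).
#' @return logical.
#' @export
positivity <- function(dot_row, pct_min = 0.5, mean_min = 1.0) {
  dot_row$pct >= pct_min && dot_row$mean_tp10k >= mean_min
}

#' Antiphase-in-DD test
#'
#' The DN2 signature: a clock gene whose DD cycling phase sits roughly 12 h
#' from its LD phase.  Phases are cosinor estimates on the timepoint-mean
#' profiles; the test requires detectable rhythmicity (relative amplitude
#' above `relamp_min`) in both conditions and fires when the circular phase
#' difference lies within `tol_h` of 12 h.
#'
#' @param ld_means,dd_means timepoint-mean expression of the clock gene in
#'   LD and DD.
#' @param hours the timepoints.
#' @param tol_h tolerance around 12 h (default 4).
#' @param relamp_min rhythmicity floor (default 0.1).
#' @param mesor_min expression floor on the cosinor mesor in TP10K (default
#'   1); the phase of a barely expressed gene is noise.
#' @return logical (`FALSE` with a warning when either condition is
#'   non-rhythmic or the gene is too weakly expressed).
#' @export
antiphase_dd_test <- function(ld_means, dd_means, hours, tol_h = 4,
                              relamp_min = 0.1, mesor_min = 1) {
  ld <- cosinor_phase(ld_means, hours)
  dd <- cosinor_phase(dd_means, hours)
  if (is.na(ld$mesor) || is.na(dd$mesor) ||
      ld$mesor < mesor_min || dd$mesor < mesor_min) {
    warning("gene expression below the mesor floor; antiphase test is FALSE")
    return(FALSE)
  }
  if (is.na(ld$relamp) || is.na(dd$relamp) ||
      ld$relamp < relamp_min || dd$relamp < relamp_min) {
    warning("gene not rhythmic in both conditions; antiphase test is FALSE")
    return(FALSE)
  }
  abs(circ_diff_h(dd$phase_h, ld$phase_h) - 12) <= tol_h
}

rule_fires <- function(rule, cl, dot_lookup) {
  get <- function(g) dot_lookup(cl, g)
  ok_present <- all(vapply(rule$present, function(g)
    isTRUE(positivity(get(g))), logical(1)))
  ok_absent <- all(vapply(rule$absent, function(g)
    !isTRUE(positivity(get(g))), logical(1)))
  ok_any <- !length(rule$present_any) ||
    any(vapply(rule$present_any, function(g)
      isTRUE(positivity(get(g))), logical(1)))
  ok_present && ok_absent && ok_any
}

#' Annotate clusters with anatomical identities
#'
#' Evaluates the marker rules in priority order per cluster; the first
#' satisfied rule assigns the identity.  `NPF` positivity is evaluated on LD
#' cells only (NPF rises broadly in DD).  The `antiphase_dd` rule tests the
#' clock gene's LD/DD phase shift via [antiphase_dd_test()].  Clusters no
#' rule claims fall through to the correlation fallback: they inherit the
#' identity of their best-correlated annotated cluster (Pearson on
#' `ln(mean TP10K + 1)` over the most variable genes) when that identity is
#' fallback-eligible, and are labelled with the fallback identity (DN3)
#' otherwise.
#'
#' @param dot [dot_stats()] table covering every rule gene (all cells).
#' @param profiles a [cluster_profiles()] object.
#' @param rules list of [marker_rule()]s (default [default_clock_rules()]).
#' @param dot_ld optional [dot_stats()] table computed on LD cells only,
#'   used for the genes in `ld_only_genes`.
#' @param ld_only_genes genes whose positivity is read from `dot_ld`
#'   (default `"NPF"`).
#' @param clock_gene gene for the antiphase rule (default `"tim"`).
#' @param tol_h,relamp_min antiphase-test settings.
#' @param fallback_eligible identities a fallback cluster may inherit by
#'   correlation (default `"DN3"`).
#' @param n_var_genes variable-gene count for the fallback correlation.
#' @return data.frame, one row per cluster: `cluster`, `identity`,
#'   `rule_priority`, `antiphase_dd`, `note`; per-cluster marker evidence in
#'   attribute `"evidence"`.
#' @export
annotate_clusters <- function(dot, profiles, rules = default_clock_rules(),
                              dot_ld = NULL, ld_only_genes = "NPF",
                              clock_gene = "tim", tol_h = 4,
                              relamp_min = 0.1, fallback_eligible = "DN3",
                              n_var_genes = 2000) {
  pr <- vapply(rules, `[[`, integer(1), "priority")
  if (anyDuplicated(pr)) stop("rule priorities must be unique")
  rules <- rules[order(pr)]
  cl_ids <- names(profiles)
  tp <- attr(profiles, "timepoints")

  dot_lookup <- function(cl, g) {
    src <- if (g %in% ld_only_genes && !is.null(dot_ld)) dot_ld else dot
    row <- src[src$cluster == cl & src$gene == g, , drop = FALSE]
    if (!nrow(row)) list(pct = 0, mean_tp10k = 0) else row
  }

  fallback_rule <- NULL
  calls <- data.frame(cluster = cl_ids, identity = NA_character_,
                      rule_priority = NA_integer_, antiphase_dd = FALSE,
                      note = "", stringsAsFactors = FALSE)
  for (i in seq_along(cl_ids)) {
    cl <- cl_ids[i]
    for (rule in rules) {
      if (identical(rule$special, "correlation_fallback")) {
        fallback_rule <- rule
        next
      }
      fired <- if (identical(rule$special, "antiphase_dd")) {
        pr_cl <- profiles[[cl]]
        if (is.null(pr_cl$LD) || is.null(pr_cl$DD) ||
            !clock_gene %in% rownames(pr_cl$LD)) FALSE
        else suppressWarnings(
          antiphase_dd_test(pr_cl$LD[clock_gene, ], pr_cl$DD[clock_gene, ],
                            tp, tol_h = tol_h, relamp_min = relamp_min))
      } else rule_fires(rule, cl, dot_lookup)
      if (isTRUE(fired)) {
        calls$identity[i] <- rule$identity
        calls$rule_priority[i] <- rule$priority
        calls$antiphase_dd[i] <- identical(rule$special, "antiphase_dd")
        break
      }
    }
  }

  # correlation fallback for unclaimed clusters
  pending <- which(is.na(calls$identity))
  if (length(pending)) {
    if (is.null(fallback_rule)) stop("no fallback rule and ",
                                     length(pending), " unassigned clusters")
    prof_vec <- function(cl) {
      mats <- profiles[[cl]][setdiff(names(profiles[[cl]]), "n_cells")]
      log1p(rowMeans(do.call(cbind, mats), na.rm = TRUE))
    }
    ngene <- nrow(profiles[[1]][[setdiff(names(profiles[[1]]),
                                         "n_cells")[1]]])
    V <- vapply(cl_ids, prof_vec, numeric(ngene))
    vg <- order(apply(V, 1, var), decreasing = TRUE)
    vg <- vg[seq_len(min(n_var_genes, length(vg)))]
    for (i in pending) {
      done <- which(!is.na(calls$identity))
      if (length(done)) {
        cors <- vapply(done, function(j)
          cor(V[vg, i], V[vg, j]), numeric(1))
        best <- done[which.max(cors)]
        if (calls$identity[best] %in% fallback_eligible) {
          calls$identity[i] <- calls$identity[best]
          calls$note[i] <- sprintf("fallback: r=%.3f with %s",
                                   max(cors), calls$cluster[best])
        } else {
          calls$identity[i] <- fallback_rule$identity
          calls$note[i] <- sprintf(
            "fallback: best match %s (%s, r=%.3f) not eligible",
            calls$cluster[best], calls$identity[best], max(cors))
        }
      } else {
        calls$identity[i] <- fallback_rule$identity
        calls$note[i] <- "fallback: no annotated reference"
      }
      calls$rule_priority[i] <- fallback_rule$priority
    }
  }

  rule_genes <- unique(unlist(lapply(rules, function(r)
    c(r$present, r$absent, r$present_any))))
  attr(calls, "evidence") <- lapply(setNames(cl_ids, cl_ids), function(cl)
    do.call(rbind, lapply(rule_genes, function(g)
      cbind(gene = g, as.data.frame(dot_lookup(cl, g)[c("pct", "mean_tp10k")])))))
  calls
}

#' Screen clusters for clock-gene expression
#'
#' Ranks clusters by core clock-gene expression: mean `tim` and `vri` TP10K,
#' the cosinor relative amplitude and phase of `tim` in LD, and the `Clk`
#' level at the timepoint nearest ZT2 (its expected peak).  Clusters whose
#' mean `tim` reaches `min_tim_tp10k` are marked high-confidence clock
#' clusters.
#'
#' @param profiles a [cluster_profiles()] object.
#' @param clock_genes character vector `c(tim, Clk, vri)` naming the genes.
#' @param zt_ref reference hour for the `Clk` level (default 2).
#' @param min_tim_tp10k high-confidence cutoff (default 5 TP10K).
#' @return data.frame ranked by mean clock-gene expression.
#' @export
clock_gene_screen <- function(profiles,
                              clock_genes = c(tim = "tim", Clk = "Clk",
                                              vri = "vri"),
                              zt_ref = 2, min_tim_tp10k = 5) {
  tp <- attr(profiles, "timepoints")
  nearest <- which.min(circ_diff_h(tp, zt_ref))
  rows <- lapply(names(profiles), function(cl) {
    pr <- profiles[[cl]]
    mats <- pr[setdiff(names(pr), "n_cells")]
    m <- rowMeans(do.call(cbind, mats), na.rm = TRUE)
    ld <- if (!is.null(pr$LD)) pr$LD else mats[[1]]
    timv <- ld[clock_genes[["tim"]], ]
    cs <- if (all(is.finite(timv)) && any(timv > 0))
      cosinor_phase(timv, tp) else list(phase_h = NA_real_, relamp = 0)
    data.frame(cluster = cl,
               mean_tim = m[clock_genes[["tim"]]],
               mean_vri = m[clock_genes[["vri"]]],
               tim_relamp = ifelse(is.na(cs$relamp), 0, cs$relamp),
               tim_phase_h = cs$phase_h,
               clk_at_zt2 = ld[clock_genes[["Clk"]], nearest],
               n_cells = pr$n_cells,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-(res$mean_tim + res$mean_vri)), ]
  res$rank <- seq_len(nrow(res))
  res$high_confidence <- res$mean_tim >= min_tim_tp10k
  rownames(res) <- NULL
  res
}
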