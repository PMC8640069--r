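# GSEA-style differentially methylated region detection: CpGs are ranked by
# the signed disease t statistic, each predefined region (promoter, gene
# body, CpG island) is scored with a weighted Kolmogorov-Smirnov running sum,
# significance comes from a permutation null over random member sets of equal
# size, and the leading-edge CpGs feed the region-methylation versus
# gene-expression (eQTM) correlation scan.

#' Rank CpGs by differential methylation
#'
#' Scores are the signed t statistics of the disease term from a DMP scan,
#' sorted descending; ties are broken lexicographically by CpG id so the
#' ranking is a pure function of the statistics.
#'
#' @param dmp_table An `ewas_scan` tibble (or any tibble with `feature_id`
#'   and `statistic`).
#' @return A tibble (cpg, score) in ranked order.
#' @export
rank_cpgs <- function(dmp_table) {
  if (nrow(dmp_table) == 0) rlang::abort("Empty DMP table.")
  tb <- tibble::tibble(cpg = dmp_table$feature_id,
                       score = dmp_table$statistic)
  tb <- tb[is.finite(tb$score), ]
  if (nrow(tb) == 0) rlang::abort("No finite ranking statistics.")
  tb[order(-tb$score, tb$cpg), ]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running sum: walking down the ranked list, member hits
#' increment by |score|^p normalised over the member scores, misses decrement
#' by 1/(N - n_members). The enrichment score is the running-sum value of
#' maximal absolute deviation (signed); the leading edge is the member set at
#' or before the extremum (at or after it for a negative score).
#'
#' @param ranked_scores Numeric vector of scores in ranked (descending) order.
#' @param member_positions Integer positions of the region's members in the
#'   ranked list.
#' @param weight_exponent Weighting exponent on |score| (GSEA-classic 1).
#' @return List with `es` and `leading_edge_positions`.
#' @export
enrichment_score <- function(ranked_scores, member_positions,
                             weight_exponent = 1) {
  N <- length(ranked_scores)
  idx <- sort(unique(as.integer(member_positions)))
  m <- length(idx)
  if (m < 1) rlang::abort("Need at least one member.")
  if (any(idx < 1 | idx > N)) rlang::abort("Member positions outside ranked list.")
  if (m == N) rlang::abort("Member set equals the whole ranked list; score undefined.")
  w <- abs(ranked_scores[idx])^weight_exponent
  if (sum(w) == 0) {
    rlang::abort("All member scores are zero; hit weights undefined.")
  }
  hit_cum <- cumsum(w) / sum(w)
  miss_step <- 1 / (N - m)
  k <- seq_len(m)
  # the running sum only rises at hits and falls between them, so its
  # extremes lie just after a hit (positive peaks) or just before one
  # (negative troughs); on |value| ties the extremum reached earliest in the
  # walk decides the sign, as in a literal element-by-element scan
  after <- hit_cum - (idx - k) * miss_step
  before <- c(0, hit_cum[-m]) - (idx - 1 - (k - 1)) * miss_step
  cand <- c(after, before)
  walk_pos <- c(idx, idx - 1)
  near_max <- abs(cand) >= max(abs(cand)) - 1e-9
  es <- cand[near_max][which.min(walk_pos[near_max])]
  if (es >= 0) {
    peak_at <- idx[which.max(after)]
    le <- idx[idx <= peak_at]
  } else {
    trough_at <- idx[which.min(before)]
    le <- idx[idx >= trough_at]
  }
  list(es = es, leading_edge_positions = le)
}

#' Permutation scan for differentially methylated regions
#'
#' For every region with at least `min_cpgs` members present in the ranked
#' list: observed enrichment score; a null of `n_perm` equal-size member sets
#' drawn at random from the ranked CpGs (seeded), shared across regions with
#' the same member count; permutation p-value
#' `(1 + #{|es_null| >= |es_obs|}) / (n_perm + 1)`; normalised score
#' `es / mean(|es_null|)`; Benjamini-Hochberg FDR within each region kind.
#'
#' @param dmp_table `ewas_scan` tibble used for the ranking.
#' @param region_sets Tibble from [read_gmt()] (region_id, region_kind,
#'   members list-column).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation null.
#' @param min_cpgs Minimum ranked members for a region to be reported.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return A tibble of class `dmr_scan`: region_id, region_kind, n_cpgs, es,
#'   nes, p_perm, p_fdr, direction, leading_edge (list-column of CpG ids).
#' @export
dmr_scan <- function(dmp_table, region_sets, n_perm = 999, seed = 1,
                     min_cpgs = 5, weight_exponent = 1) {
  if (n_perm < 100) rlang::abort("Use at least 100 permutations.")
  ranked <- rank_cpgs(dmp_table)
  pos_of <- stats::setNames(seq_len(nrow(ranked)), ranked$cpg)
  set.seed(as.integer(seed))
  obs_rows <- purrr::pmap(region_sets, function(region_id, region_kind, members, ...) {
    idx <- unname(pos_of[members[members %in% names(pos_of)]])
    if (length(idx) < min_cpgs) {
      rlang::inform(paste0("Skipping region ", region_id, ": fewer than ",
                           min_cpgs, " ranked CpGs."))
      return(NULL)
    }
    obs <- enrichment_score(ranked$score, idx, weight_exponent)
    tibble::tibble(
      region_id = region_id, region_kind = region_kind,
      n_cpgs = length(idx), es = obs$es,
      direction = if (obs$es >= 0) "hyper" else "hypo",
      leading_edge = list(ranked$cpg[obs$leading_edge_positions]))
  })
  res <- dplyr::bind_rows(obs_rows)
  if (nrow(res) > 0) {
    # permutation null shared across regions of equal member count: n_perm
    # random member sets per size, so p-values well below 1/m are attainable
    # at fixed cost
    null_by_size <- lapply(split(seq_len(nrow(res)), res$n_cpgs), function(ii) {
      sz <- res$n_cpgs[ii[1]]
      vapply(seq_len(n_perm), function(b) {
        abs(enrichment_score(ranked$score, sample.int(nrow(ranked), sz),
                             weight_exponent)$es)
      }, numeric(1))
    })
    res$p_perm <- NA_real_
    res$nes <- NA_real_
    for (sz in names(null_by_size)) {
      ii <- which(res$n_cpgs == as.integer(sz))
      nl <- null_by_size[[sz]]
      res$p_perm[ii] <- vapply(res$es[ii], function(e) {
        (1 + sum(nl >= abs(e))) / (n_perm + 1)
      }, numeric(1))
      res$nes[ii] <- res$es[ii] / mean(nl)
    }
  }
  if (nrow(res) == 0) {
    rlang::warn("No region had enough ranked CpGs.")
    return(structure(res, class = c("dmr_scan", class(res))))
  }
  res <- dplyr::mutate(dplyr::group_by(res, .data$region_kind),
                       p_fdr = stats::p.adjust(.data$p_perm, "BH"))
  res <- dplyr::arrange(dplyr::ungroup(res), .data$p_perm)
  structure(res, class = c("dmr_scan", class(res)), n_perm = n_perm)
}

#' Per-sample mean methylation over a leading edge
#'
#' @param methylation Beta matrix (CpG x sample).
#' @param leading_edge Character vector of CpG ids.
#' @return Named numeric vector, one mean beta per sample.
#' @export
leading_edge_profile <- function(methylation, leading_edge) {
  if (length(leading_edge) == 0) rlang::abort("Empty leading edge.")
  missing <- setdiff(leading_edge, rownames(methylation))
  if (length(missing) > 0) {
    rlang::abort(paste0("CpG(s) absent from matrix: ",
                        paste(head(missing, 3), collapse = ", ")))
  }
  colMeans(methylation[leading_edge, , drop = FALSE])
}

#' Correlate region methylation with nearby gene expression (eQTM)
#'
#' For each significant region, the leading-edge CpGs are averaged per sample
#' and Pearson-correlated with log-scale expression of every gene whose TSS
#' lies within `window` bp of the region span (min to max member CpG
#' position, boundary inclusive). Optionally stratified by disease group.
#'
#' @param dmr_table `dmr_scan` tibble (leading_edge list-column).
#' @param methylation Beta matrix.
#' @param expression_log Log-scale expression matrix (see [vst_transform()]).
#' @param gene_annotation Tibble feature_id/chrom/pos (TSS, strand-aware).
#' @param cpg_annotation Tibble feature_id/chrom/pos for CpGs.
#' @param window Pairing distance in bp (default 1500).
#' @param sheet Optional sample sheet; when given, per-group correlations for
#'   cases and controls are added.
#' @return A tibble of class `eqtm_scan`: region_id, gene_id, pearson_r, p,
#'   n (+ r_case/p_case/r_control/p_control when stratified), flagged for
#'   zero-variance profiles.
#' @export
eqtm_scan <- function(dmr_table, methylation, expression_log, gene_annotation,
                      cpg_annotation, window = 1500, sheet = NULL) {
  cpg_pos <- stats::setNames(cpg_annotation$pos, cpg_annotation$feature_id)
  cpg_chr <- stats::setNames(cpg_annotation$chrom, cpg_annotation$feature_id)
  shared <- intersect(colnames(methylation), colnames(expression_log))
  if (length(shared) == 0) rlang::abort("No shared samples between layers.")
  rows <- purrr::pmap(dmr_table, function(region_id, leading_edge, ...) {
    le <- leading_edge[leading_edge %in% names(cpg_pos)]
    if (length(le) == 0) return(NULL)
    span <- range(cpg_pos[le])
    chr <- cpg_chr[le][1]
    cand <- gene_annotation[gene_annotation$chrom == chr &
                              gene_annotation$pos >= span[1] - window &
                              gene_annotation$pos <= span[2] + window, ]
    cand <- cand[cand$feature_id %in% rownames(expression_log), ]
    if (nrow(cand) == 0) return(NULL)
    prof <- leading_edge_profile(methylation[, shared, drop = FALSE], le)
    purrr::map_dfr(cand$feature_id, function(g) {
      e <- expression_log[g, shared]
      corr_row(region_id, g, prof, e, shared, sheet)
    })
  })
  res <- dplyr::bind_rows(rows)
  structure(res, class = c("eqtm_scan", class(res)), window = window)
}

corr_row <- function(region_id, gene_id, prof, e, shared, sheet) {
  base <- safe_cor(prof, e)
  out <- tibble::tibble(region_id = region_id, gene_id = gene_id,
                        pearson_r = base$r, p = base$p, n = length(shared),
                        flagged = base$flagged)
  if (!is.null(sheet)) {
    grp <- sheet$disease[match(shared, sheet$sample_id)]
    ca <- safe_cor(prof[grp == "case"], e[grp == "case"])
    co <- safe_cor(prof[grp == "control"], e[grp == "control"])
    out$r_case <- ca$r; out$p_case <- ca$p
    out$r_control <- co$r; out$p_control <- co$p
  }
  out
}

safe_cor <- function(x, y) {
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, flagged = TRUE))
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
}
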