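#' Scan a gene's control region for pattern-generating windows
#'
#' Slides a window (default 1 kbp, stepping 500 bp; the final partial window
#' is dropped) across the control region. Each window is scored with every
#' TF motif ([crm_motif_score()]), its expression profile is predicted from
#' the trained model weights using a window-level baseline (the mean of the
#' trained CRM baselines, since scanned windows have no trained baseline of
#' their own), and the prediction is compared to the gene's endogenous
#' pattern by PGP with domain selection ([select_domains()]).
#'
#' @param gene_expr Binary [axis_profile()] of the gene's endogenous
#'   pattern (must contain at least one expressed bin).
#' @param region DNA sequence of the control region (>= `window` bp).
#' @param model Trained [regression_model()].
#' @param motifs Named list of [motif_model()]s covering the model's TFs.
#' @param concentrations Named list of continuous [axis_profile()]s.
#' @param window,step Scan window width and step in bp (defaults 1000/500).
#' @param gene Gene label recorded on the predictions.
#' @param seq_id Sequence id for the window coordinates.
#' @return A `crm_predictions` data frame, one row per window, sorted by
#'   decreasing PGP: columns `gene`, `seq_id`, `start`, `end`, `pgp`,
#'   `reward`, `penalty`, one `S_<tf>` column per TF; attributes `S`
#'   (window x TF score matrix) and `predicted` (list of predicted
#'   profiles, in window order before sorting is applied to both).
#' @export
scan_locus <- function(gene_expr, region, model, motifs, concentrations,
                       window = 1000L, step = 500L, gene = "gene",
                       seq_id = "locus") {
  ev <- profile_values(gene_expr, length_of(gene_expr))
  if (!any(ev == 1)) stop("gene expression pattern is all zero")
  L <- nchar(region)
  if (L < window) stop("control region shorter than the scan window")
  tfs <- unique(model$covariate_spec$tf)
  if (!all(tfs %in% names(motifs))) {
    stop("missing motif for TF: ",
         paste(setdiff(tfs, names(motifs)), collapse = ", "))
  }
  alpha <- mean(model$baselines)
  starts <- seq(0L, L - window, by = step)
  S <- matrix(NA_real_, length(starts), length(tfs),
              dimnames = list(NULL, tfs))
  preds <- vector("list", length(starts))
  out <- data.frame(gene = gene, seq_id = seq_id, start = starts,
                    end = starts + window, pgp = NA_real_,
                    reward = NA_real_, penalty = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(starts)) {
    win_seq <- substr(region, starts[i] + 1, starts[i] + window)
    S[i, ] <- vapply(tfs, function(tf) crm_motif_score(win_seq, motifs[[tf]]),
                     numeric(1))
    pred <- predict_expression(model, row_of(S, i), concentrations, alpha = alpha)
    sel <- select_domains(pred, gene_expr)
    preds[[i]] <- pred
    out$pgp[i] <- sel$result$pgp
    out$reward[i] <- sel$result$reward
    out$penalty[i] <- sel$result$penalty
  }
  for (tf in tfs) out[[paste0("S_", tf)]] <- S[, tf]
  ord <- order(-out$pgp, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, S = S[ord, , drop = FALSE], predicted = preds[ord],
            class = c("crm_predictions", "data.frame"))
}

#' Empirical p-value of a PGP score against a background scan
#'
#' `p = (1 + #(null >= pgp)) / (1 + N)`: the add-one-corrected frequency of
#' background windows scoring at least as high, so p is never 0 and is
#' uniform on (0, 1\] under the null.
#'
#' @param pgp_value PGP score(s) to assess (vectorized).
#' @param null_scores Non-empty numeric vector of PGP scores from a
#'   background (genome-wide) scan against the same expression pattern.
#' @return Empirical p-value(s) in (0, 1\].
#' @export
empirical_pvalue <- function(pgp_value, null_scores) {
  if (!length(null_scores)) stop("null score set is empty")
  vapply(pgp_value, function(v) {
    (1 + sum(null_scores >= v)) / (1 + length(null_scores))
  }, numeric(1))
}

#' Activator-presence filter for scanned windows
#'
#' A candidate window is retained only if at least one of the model's
#' activators shows above-average binding-site presence, i.e. a motif
#' z-score (against the genome-wide window distribution) greater than 0.
#'
#' @param window_z Named numeric vector of per-TF z-scores for one window.
#' @param activators Non-empty character vector of activator TF names.
#' @return `TRUE` (keep) or `FALSE` (discard).
#' @export
activator_filter <- function(window_z, activators) {
  if (!length(activators)) stop("activator list is empty")
  if (!all(activators %in% names(window_z))) {
    stop("missing z-score for activator: ",
         paste(setdiff(activators, names(window_z)), collapse = ", "))
  }
  any(window_z[activators] > 0)
}

#' Call CRMs from scored window predictions
#'
#' Retains windows with empirical p-value below the threshold whose filters
#' passed, then merges overlapping retained windows into single calls,
#' keeping the lowest-p window (ties: highest PGP) as the representative of
#' each merged cluster.
#'
#' @param predictions A `crm_predictions` data frame carrying columns
#'   `empirical_p` and (optionally) `filters_passed`.
#' @param p_threshold Retention threshold on the empirical p-value
#'   (default 0.015).
#' @return The called subset, one row per merged cluster, with added columns
#'   `merged_start` / `merged_end` spanning the cluster.
#' @export
call_crms <- function(predictions, p_threshold = 0.015) {
  if (!"empirical_p" %in% names(predictions)) {
    stop("predictions must carry an 'empirical_p' column")
  }
  keep <- predictions$empirical_p < p_threshold
  if ("filters_passed" %in% names(predictions)) {
    keep <- keep & predictions$filters_passed
  }
  hits <- predictions[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(hits$seq_id, hits$start), , drop = FALSE]
  cluster <- integer(nrow(hits))
  cid <- 1L
  cluster[1] <- cid
  for (i in seq_len(nrow(hits))[-1]) {
    same <- hits$seq_id[i] == hits$seq_id[i - 1] &&
      hits$start[i] < max(hits$end[cluster == cid])
    if (!same) cid <- cid + 1L
    cluster[i] <- cid
  }
  calls <- do.call(rbind, lapply(split(hits, cluster), function(g) {
    rep_row <- g[order(g$empirical_p, -g$pgp)[1], , drop = FALSE]
    rep_row$merged_start <- min(g$start)
    rep_row$merged_end <- max(g$end)
    rep_row
  }))
  rownames(calls) <- NULL
  calls
}

#' Enrichment of sibling CRMs by Fisher's exact test
#'
#' Two-sided Fisher exact test on the 2x2 contingency table
#' `[[a, b], [c, d]]` (e.g. real vs random gene sets crossed with
#' solitary vs redundant CRM predictions).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-major.
#' @return Two-sided exact p-value.
#' @export
sibling_enrichment <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("degenerate (all-zero) table")
  fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}
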