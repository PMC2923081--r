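# deterministic sub-seed for a (tf, crm) pair so edge tests are reproducible
# independently of evaluation order
pair_seed <- function(seed, tf, crm) {
  h <- sum(utf8ToInt(paste(tf, crm, sep = "\r")) *
             (31^(seq_len(nchar(paste(tf, crm, sep = "\r"))) %% 7)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Permutation test for one TF -> CRM regulatory edge
#'
#' Computes the root-mean-square error (RMSE) between the model's wild-type
#' prediction for the CRM and its true binary profile, then repeatedly
#' permutes the TF's 100-bin concentration profile (without replacement),
#' re-predicts, and recomputes the RMSE. The empirical p-value
#' `p = (1 + #(null RMSE <= RMSE_wt)) / (1 + n_perm)` measures how important
#' the factor's spatial concentration profile is to the CRM's pattern: ties
#' count as extreme, so a TF whose motif score in the CRM is zero (whose
#' permutations cannot change the prediction) gets p = 1.
#'
#' @param model Fitted [regression_model()].
#' @param tf TF to test.
#' @param crm CRM name (must have a trained baseline, or supply `alpha`).
#' @param S_row Named motif-score vector for the CRM.
#' @param concentrations Named list of continuous [axis_profile()]s.
#' @param target Binary [axis_profile()] of the CRM's true pattern.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param alpha Optional explicit baseline.
#' @return A list of class `edge_test`: `tf`, `crm`, `rmse_wt`, `null_rmse`
#'   (length `n_perm`), `p`, `sign` (`"activator"` or `"repressor"` from the
#'   sign of the TF's first-order weight).
#' @export
edge_pvalue <- function(model, tf, crm, S_row, concentrations, target,
                        n_perm = 1000L, seed = 1L, alpha = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  C <- conc_matrix(concentrations)
  if (!tf %in% rownames(C)) stop("unknown TF: ", tf)
  y <- profile_values(target, ncol(C))
  rmse_of <- function(Cm) {
    pred <- predict_expression(model, S_row, Cm, crm = crm, alpha = alpha)
    sqrt(mean((pred$values - y)^2))
  }
  rmse_wt <- rmse_of(C)
  withr::local_seed(pair_seed(seed, tf, crm))
  null_rmse <- vapply(seq_len(n_perm), function(i) {
    Cp <- C
    Cp[tf, ] <- C[tf, sample(ncol(C))]
    rmse_of(Cp)
  }, numeric(1))
  w <- model$weights[[tf]]
  structure(list(tf = tf, crm = crm, rmse_wt = rmse_wt,
                 null_rmse = null_rmse,
                 p = (1 + sum(null_rmse <= rmse_wt)) / (1 + n_perm),
                 sign = if (w >= 0) "activator" else "repressor"),
            class = "edge_test")
}

#' @export
print.edge_test <- function(x, ...) {
  cat(sprintf("<edge_test> %s -> %s: RMSE_wt %.4f, p %.4g (%s)\n",
              x$tf, x$crm, x$rmse_wt, x$p, x$sign))
  invisible(x)
}

#' Assemble the TF -> CRM regulatory network
#'
#' Runs [edge_pvalue()] for every (TF, CRM) pair and retains edges with
#' empirical p below `alpha_level`. Edge signs (activating / repressing)
#' come from the sign of the TF's fitted weight.
#'
#' @inheritParams edge_pvalue
#' @param S CRM x TF motif-score matrix.
#' @param targets Named list of binary [axis_profile()]s per CRM.
#' @param alpha_level Significance threshold on the edge p-value
#'   (default 0.05).
#' @return Data frame of significant edges: `tf`, `crm`, `p`, `sign`,
#'   `rmse_wt`; attribute `all_edges` holds the full table for every pair.
#' @export
build_network <- function(model, S, concentrations, targets,
                          alpha_level = 0.05, n_perm = 1000L, seed = 1L) {
  tfs <- unique(model$covariate_spec$tf)
  crms <- rownames(S)
  rows <- list()
  for (crm in crms) {
    for (tf in tfs) {
      et <- edge_pvalue(model, tf, crm, row_of(S, crm), concentrations,
                        targets[[crm]], n_perm = n_perm, seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        tf = tf, crm = crm, p = et$p, sign = et$sign,
        rmse_wt = et$rmse_wt, stringsAsFactors = FALSE)
    }
  }
  all_edges <- do.call(rbind, rows)
  sig <- all_edges[all_edges$p < alpha_level, , drop = FALSE]
  rownames(sig) <- NULL
  structure(sig, all_edges = all_edges)
}

#' ChIP bound-vs-random motif-score discrimination
#'
#' One-sided Wilcoxon rank-sum test that the motif scores of ChIP-bound
#' regions are stochastically greater than those of random length-matched
#' regions.
#'
#' @param bound_scores,random_scores Non-empty numeric score vectors.
#' @return One-sided p-value.
#' @export
chip_discrimination <- function(bound_scores, random_scores) {
  if (!length(bound_scores) || !length(random_scores)) {
    stop("score vectors must be non-empty")
  }
  suppressWarnings(
    wilcox.test(bound_scores, random_scores,
                alternative = "greater")$p.value)
}

#' Positional motif-score summary along the axis
#'
#' For each axis bin, averages a TF's motif score over the CRMs active
#' (expressed) in that bin, and correlates the resulting positional profile
#' with the TF's concentration profile. Activators tend to correlate
#' positively (their sites sit in CRMs active where the factor is present);
#' repressors anti-correlate.
#'
#' @param scores Named numeric vector: the TF's motif score per CRM.
#' @param targets Named list of binary [axis_profile()]s per CRM.
#' @param concentration Continuous [axis_profile()] of the TF.
#' @return List: `mean_score` (per-bin mean, `NA` where no CRM is active),
#'   `n_active` (CRMs active per bin), `correlation` (Pearson, over bins
#'   with at least one active CRM; `NA` with a message attribute if the
#'   positional profile has zero variance).
#' @export
positional_motif_summary <- function(scores, targets, concentration) {
  cvals <- profile_values(concentration, length_of(concentration))
  B <- length(cvals)
  E <- do.call(rbind, lapply(names(scores), function(l) {
    profile_values(targets[[l]], B)
  }))
  n_active <- colSums(E)
  if (all(n_active == 0)) stop("no CRM is active in any bin")
  mean_score <- ifelse(n_active > 0,
                       as.numeric(crossprod(E, scores)) / n_active, NA_real_)
  ok <- !is.na(mean_score)
  correlation <- if (sd(mean_score[ok]) > 0 && sd(cvals[ok]) > 0) {
    cor(mean_score[ok], cvals[ok])
  } else NA_real_
  list(mean_score = mean_score, n_active = n_active,
       correlation = correlation)
}

#' Classify incongruous repressor occupancy at CRMs
#'
#' A repressor's occupancy of a CRM is "incongruous" when the CRM is active
#' (expressed) inside the repressor's own expression domain even though the
#' factor is bound there. Each case is annotated with the strength of motif
#' support from the genome-standardized z-score: `"significant"` (z > 2,
#' more than 2 SD above the genomic mean), `"weak"` (0 < z <= 2), or
#' `"absent"` (z <= 0).
#'
#' @param activity Binary [axis_profile()] of the CRM.
#' @param repressor_domains Named list (per repressor) of data frames with
#'   columns `start`, `end`: the repressor's expression domain(s) in bins.
#' @param occupancy Named logical vector: is the repressor experimentally
#'   bound at the CRM?
#' @param motif_z Named numeric vector of genome-standardized motif z-scores
#'   for the CRM.
#' @return Data frame with one row per repressor: `repressor`, `overlap`,
#'   `occupied`, `incongruous`, `motif_support`.
#' @export
incongruous_occupancy <- function(activity, repressor_domains, occupancy,
                                  motif_z) {
  act <- profile_values(activity, length_of(activity))
  reps <- names(occupancy)
  miss <- setdiff(reps, names(repressor_domains))
  if (length(miss)) stop("unknown repressor: ", paste(miss, collapse = ", "))
  out <- lapply(reps, function(r) {
    dom <- repressor_domains[[r]]
    in_dom <- rep(FALSE, length(act))
    for (i in seq_len(nrow(dom))) in_dom[dom$start[i]:dom$end[i]] <- TRUE
    overlap <- any(act == 1 & in_dom)
    z <- motif_z[[r]]
    data.frame(repressor = r, overlap = overlap,
               occupied = as.logical(occupancy[[r]]),
               incongruous = overlap && isTRUE(as.logical(occupancy[[r]])),
               motif_support = if (z > 2) "significant"
                               else if (z > 0) "weak" else "absent",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export a network edge table as TSV
#'
#' @param edges Edge data frame from [build_network()].
#' @param path Output path.
#' @export
write_network <- function(edges, path) {
  write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
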