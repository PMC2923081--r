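#' Pattern-Generating Potential (PGP) score
#'
#' Compares a predicted expression profile (values in \[0, 1\]) against a
#' binary endogenous profile. The *reward* is the mean predicted expression
#' over bins where the gene is expressed; the *penalty* is the mean predicted
#' expression over bins where it is not. The two are combined as
#'
#' `PGP = 0.5 + 0.5 * (reward - penalty_weight * penalty)`
#'
#' with `penalty_weight = 3` by default (false expression is penalized three
#' times as heavily as correct expression is rewarded), so PGP ranges from
#' -1 (prediction exactly complementary to the pattern) through 0.5 (flat
#' zero prediction) to 1 (perfect match).
#'
#' @param predicted Continuous [axis_profile()] (or numeric vector in
#'   \[0, 1\]) of predicted expression.
#' @param endogenous Binary [axis_profile()] (or 0/1 vector) with at least
#'   one expressed and one non-expressed bin.
#' @param penalty_weight Relative weight of the penalty term (default 3).
#' @param mask Optional logical vector marking bins to exclude from both
#'   terms ("don't care" bins; used by [select_domains()]).
#' @return A list of class `pgp_result`: `reward`, `penalty`, `pgp`,
#'   `selected_domains` (bin ranges of the expression domains entering the
#'   reward term).
#' @examples
#' e <- rep(0, 100); e[40:60] <- 1
#' pgp(e, e)$pgp        # perfect match: 1
#' pgp(rep(0, 100), e)$pgp  # flat zero: 0.5
#' @export
pgp <- function(predicted, endogenous, penalty_weight = 3, mask = NULL) {
  p <- profile_values(predicted, n_bins = length_of(predicted))
  e <- profile_values(endogenous, n_bins = length(p))
  if (!all(e %in% c(0, 1))) stop("endogenous profile must be binary")
  if (any(p < 0 | p > 1)) stop("predicted values must lie in [0, 1]")
  use <- if (is.null(mask)) rep(TRUE, length(e)) else !mask
  if (!any(e[use] == 1)) stop("endogenous profile has no expression bin")
  if (!any(e[use] == 0)) stop("endogenous profile has no non-expression bin")
  reward <- mean(p[use & e == 1])
  penalty <- mean(p[use & e == 0])
  eb <- e; eb[!use] <- 0
  structure(list(reward = reward, penalty = penalty,
                 pgp = 0.5 + 0.5 * (reward - penalty_weight * penalty),
                 selected_domains = profile_domains(eb)),
            class = "pgp_result")
}

length_of <- function(x) if (is_axis_profile(x)) length(x$values) else length(x)

#' @export
print.pgp_result <- function(x, ...) {
  cat(sprintf("<pgp_result> PGP %.4f (reward %.4f, penalty %.4f), %d domain(s)\n",
              x$pgp, x$reward, x$penalty, nrow(x$selected_domains)))
  invisible(x)
}

#' PGP with selection of endogenous expression domains
#'
#' A CRM may drive only a subset of its gene's expression domains. This
#' routine decomposes the endogenous profile into maximal runs of expressed
#' bins, evaluates the PGP for every non-empty subset of domains -- bins of
#' unselected domains are excluded from both the reward and the penalty
#' ("don't care") -- and returns the subset maximizing the PGP. For more
#' than `max_exhaustive` domains a greedy forward selection is used. Ties
#' are broken deterministically: fewer domains first, then the anterior-most
#' combination.
#'
#' @inheritParams pgp
#' @param max_exhaustive Largest domain count for exhaustive subset search
#'   (default 12).
#' @return A list with elements `endogenous` (binary [axis_profile()] with
#'   only the selected domains set) and `result` (the best `pgp_result`).
#' @export
select_domains <- function(predicted, endogenous, penalty_weight = 3,
                           max_exhaustive = 12L) {
  p <- profile_values(predicted, n_bins = length_of(predicted))
  e <- profile_values(endogenous, n_bins = length(p))
  doms <- profile_domains(e)
  nd <- nrow(doms)
  if (nd == 0) stop("endogenous profile has no expression domain")

  dom_bins <- lapply(seq_len(nd), function(i) doms$start[i]:doms$end[i])
  eval_subset <- function(sel) {
    mask <- rep(FALSE, length(e))
    for (i in setdiff(seq_len(nd), sel)) mask[dom_bins[[i]]] <- TRUE
    pgp(p, e, penalty_weight = penalty_weight, mask = mask)
  }

  if (nd <= max_exhaustive) {
    subsets <- unlist(lapply(seq_len(nd), function(k) {
      utils::combn(nd, k, simplify = FALSE)
    }), recursive = FALSE)
    results <- lapply(subsets, eval_subset)
    scores <- vapply(results, `[[`, numeric(1), "pgp")
    # tie-break: fewer domains, then anterior-most (lexicographic indices)
    ord <- order(-scores,
                 vapply(subsets, length, integer(1)),
                 vapply(subsets, function(s) {
                   sum(s * nd^rev(seq_along(s) - 1))
                 }, numeric(1)))
    best <- ord[1]
    sel <- subsets[[best]]
    res <- results[[best]]
  } else {
    sel <- integer(0)
    res <- NULL
    repeat {
      cand <- setdiff(seq_len(nd), sel)
      if (!length(cand)) break
      trials <- lapply(cand, function(i) eval_subset(sort(c(sel, i))))
      sc <- vapply(trials, `[[`, numeric(1), "pgp")
      best <- which(sc == max(sc))[1]  # anterior-most among equal gains
      if (!is.null(res) && sc[best] <= res$pgp) break
      sel <- sort(c(sel, cand[best]))
      res <- trials[[best]]
    }
  }
  eb <- rep(0, length(e))
  for (i in sel) eb[dom_bins[[i]]] <- 1
  list(endogenous = axis_profile(eb, "binary", "selected",
                                 n_bins = length(e)),
       result = res)
}
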