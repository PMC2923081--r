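# Sequence <-> integer codes: A,C,G,T -> 1..4, N -> 0
encode_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty sequence")
  codes <- match(strsplit(sequence, "")[[1]], c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 0L
  if (any(!strsplit(sequence, "")[[1]] %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  as.integer(codes)
}

#' HMM motif score of a sequence window
#'
#' Scores a sequence against a two-state hidden Markov model in the style of
#' the Stubb program: at each position the model either emits a background
#' base (probability `1 - q`) or enters a non-overlapping motif site
#' (probability `q/2` per strand) emitting `width` bases from the PWM
#' columns (reverse-complemented on the minus strand). The score is the
#' log-likelihood ratio
#' `log P(seq | site model) - log P(seq | background only)`.
#'
#' With `fit_transition = TRUE` the site-entry probability `q` is chosen by
#' maximum likelihood over `[0, q_max]`; since `q = 0` reduces the model to
#' pure background, the fitted score is always `>= 0`. `N` bases are emitted
#' with probability 1 under both states and contribute nothing to the score.
#'
#' @param sequence DNA string over `{A,C,G,T,N}`, length >= motif width.
#' @param motif A [motif_model()].
#' @param fit_transition Fit `q` by maximum likelihood (default `TRUE`)?
#'   Otherwise `q` must be supplied.
#' @param q Fixed site-entry probability when `fit_transition = FALSE`.
#' @param q_max Upper bound for the fitted `q` (default 0.1).
#' @return The log-likelihood-ratio score (a single number). With
#'   `fit_transition = TRUE`, attribute `q` carries the fitted value.
#' @examples
#' m <- motif_model(matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 4))  # consensus AC
#' window_hmm_score("TTTTACTTTTACTTTT", m)
#' @export
window_hmm_score <- function(sequence, motif, fit_transition = TRUE,
                             q = NULL, q_max = 0.1) {
  stopifnot(inherits(motif, "motif_model"))
  codes <- encode_sequence(sequence)
  if (length(codes) < motif$width) {
    stop("sequence (", length(codes), " bp) shorter than motif width (",
         motif$width, ")")
  }
  logfreq <- log(motif$freq)
  logbg <- log(motif$background)
  llr <- function(qq) hmm_llr_cpp(codes, logfreq, logbg, qq)
  if (!fit_transition) {
    if (is.null(q)) stop("supply q when fit_transition = FALSE")
    return(llr(q))
  }
  # 1-D maximum likelihood for q on [0, q_max]; the boundary q = 0
  # (pure background, score 0) is always admissible.
  opt <- optimize(llr, c(0, q_max), maximum = TRUE, tol = 1e-7)
  cand_q <- c(0, opt$maximum, q_max)
  cand_s <- c(0, opt$objective, llr(q_max))
  best <- which.max(cand_s)
  structure(max(cand_s[best], 0), q = cand_q[best])
}

#' Tile a sequence into fixed windows and score each with a motif
#'
#' Windows of `window` bp are placed every `shift` bp from the start of the
#' sequence; a final partial window is dropped. Each window is scored with
#' [window_hmm_score()].
#'
#' @inheritParams window_hmm_score
#' @param window Window width in bp (default 500).
#' @param shift Step between window starts in bp (default 250).
#' @param seq_id Sequence identifier for the window coordinates.
#' @param species Species tag stored on the profile.
#' @return A `motif_profile`: a data frame with columns `seq_id`, `start`,
#'   `end` (0-based half-open), `score`, plus attributes `tf_name`,
#'   `species`, `window`, `shift`.
#' @export
profile_sequence <- function(sequence, motif, window = 500L, shift = 250L,
                             fit_transition = TRUE, q = NULL, q_max = 0.1,
                             seq_id = "seq", species = "ref") {
  L <- nchar(sequence)
  if (window < motif$width) stop("window smaller than motif width")
  if (L < window) stop("sequence shorter than one window")
  starts <- seq(0L, L - window, by = shift)
  scores <- vapply(starts, function(s) {
    as.numeric(window_hmm_score(substr(sequence, s + 1, s + window), motif,
                                fit_transition = fit_transition, q = q,
                                q_max = q_max))
  }, numeric(1))
  new_motif_profile(data.frame(seq_id = seq_id, start = starts,
                               end = starts + window, score = scores,
                               stringsAsFactors = FALSE),
                    tf_name = motif$name, species = species,
                    window = window, shift = shift)
}

new_motif_profile <- function(df, tf_name, species, window, shift) {
  structure(df, tf_name = tf_name, species = species, window = window,
            shift = shift, class = c("motif_profile", "data.frame"))
}

#' Motif score of one CRM sequence
#'
#' The whole CRM sequence is scored as a single window with
#' [window_hmm_score()]; the result is the per-factor CRM score that enters
#' the expression model as the motif-score covariate.
#'
#' @inheritParams window_hmm_score
#' @param crm_sequence CRM DNA sequence (typically about 1 kbp).
#' @return Numeric score.
#' @export
crm_motif_score <- function(crm_sequence, motif, fit_transition = TRUE,
                            q = NULL, q_max = 0.1) {
  as.numeric(window_hmm_score(crm_sequence, motif,
                              fit_transition = fit_transition, q = q,
                              q_max = q_max))
}

#' Standardize a motif profile against its genome-wide distribution
#'
#' Converts window scores to z-scores against the mean and (population)
#' standard deviation of all windows in the profile, and labels each window
#' `"significant"` (z > 2, i.e. more than 2 SD above the genomic mean),
#' `"weak"` (0 < z <= 2) or `"absent"` (z <= 0).
#'
#' @param profile A `motif_profile` from [profile_sequence()] with at least
#'   two windows.
#' @return The profile with added columns `z` and `category`.
#' @export
standardize_scores <- function(profile) {
  if (!inherits(profile, "motif_profile")) stop("not a motif_profile")
  s <- profile$score
  if (length(s) < 2) stop("need at least 2 windows to standardize")
  mu <- mean(s)
  sigma <- sqrt(mean((s - mu)^2))
  if (sigma == 0) stop("zero score variance: cannot standardize")
  profile$z <- (s - mu) / sigma
  profile$category <- ifelse(profile$z > 2, "significant",
                             ifelse(profile$z > 0, "weak", "absent"))
  profile
}

#' Write / read motif profiles as TSV
#'
#' Columns: `seq_id`, `start`, `end`, `score` and, when present, `z` and
#' `category`, with a header line.
#'
#' @param profile A `motif_profile`.
#' @param path File path.
#' @export
write_motif_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_motif_profile
#' @param tf_name,species Metadata to attach on read.
#' @export
read_motif_profile <- function(path, tf_name = "", species = "ref") {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  w <- if (nrow(df)) df$end[1] - df$start[1] else NA_integer_
  sh <- if (nrow(df) > 1) df$start[2] - df$start[1] else NA_integer_
  new_motif_profile(df, tf_name = tf_name, species = species,
                    window = w, shift = sh)
}
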