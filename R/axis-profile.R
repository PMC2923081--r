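#' Expression / concentration profiles along the anterior-posterior axis
#'
#' An `axis_profile` holds one value per bin along the anterior-posterior
#' (A/P) body axis, divided into `n_bins` equal bins (default 100). Bin 1 is
#' the most anterior position, bin `n_bins` the most posterior. Profiles are
#' either `"binary"` (endogenous expression: 0/1 per bin) or `"continuous"`
#' (TF concentrations or predicted expression, values in \[0, 1\]).
#'
#' @param values Numeric vector of bin values in \[0, 1\].
#' @param kind `"binary"` or `"continuous"`.
#' @param label Character label (gene, CRM or TF name).
#' @param n_bins Required profile length (default 100).
#' @return An object of class `axis_profile`: a list with elements
#'   `values`, `kind`, `label`.
#' @examples
#' axis_profile(rep(c(0, 1, 0), c(39, 21, 40)), "binary", "stripe")
#' @export
axis_profile <- function(values, kind = c("continuous", "binary"),
                         label = "", n_bins = 100L) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) != n_bins) {
    stop("axis profile must have exactly ", n_bins, " bins, got ",
         length(values))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("axis profile values must be finite")
  }
  if (any(values < 0 | values > 1)) {
    stop("axis profile values must lie in [0, 1]")
  }
  if (kind == "binary" && !all(values %in% c(0, 1))) {
    stop("binary axis profile may contain only 0/1 values")
  }
  structure(list(values = values, kind = kind, label = as.character(label)),
            class = "axis_profile")
}

#' @export
print.axis_profile <- function(x, ...) {
  cat(sprintf("<axis_profile> %s (%s), %d bins, mean %.3f\n",
              x$label, x$kind, length(x$values), mean(x$values)))
  invisible(x)
}

is_axis_profile <- function(x) inherits(x, "axis_profile")

# coerce an axis_profile or bare numeric vector to bin values
profile_values <- function(x, n_bins = 100L) {
  v <- if (is_axis_profile(x)) x$values else as.numeric(x)
  if (length(v) != n_bins) stop("profile must have ", n_bins, " bins")
  v
}

#' Expression domains of a binary profile
#'
#' A domain is a maximal run of consecutive bins with value 1.
#'
#' @param profile A binary [axis_profile()] or 0/1 vector.
#' @return Data frame with columns `start`, `end` (1-based inclusive bin
#'   indices), one row per domain; zero rows if the profile is all zero.
#' @export
profile_domains <- function(profile) {
  v <- profile_values(profile, n_bins = if (is_axis_profile(profile))
    length(profile$values) else length(profile))
  if (!all(v %in% c(0, 1))) stop("domains are defined for binary profiles")
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1
  data.frame(start = starts[keep], end = ends[keep])
}

#' Discretize an intensity trace into a binary 100-bin profile
#'
#' Averages a raw anterior-to-posterior intensity trace (e.g. extracted from
#' a standardized embryo image) into `n_bins` equal-sized bins, then calls a
#' bin "expressed" when its mean intensity exceeds `threshold_frac` times the
#' maximum bin mean. Contiguous runs of expressed bins form expression
#' domains.
#'
#' @param intensity Non-negative numeric vector, length >= `n_bins`,
#'   ordered anterior to posterior.
#' @param n_bins Number of axis bins (default 100).
#' @param threshold_frac Fraction of the maximum bin mean above which a bin
#'   is called expressed (default 0.25).
#' @param label Label for the resulting profile.
#' @return A binary [axis_profile()] with attribute `domains` (the data
#'   frame from [profile_domains()]). An all-zero trace yields an all-zero
#'   profile with zero domains.
#' @export
binarize_profile <- function(intensity, n_bins = 100L, threshold_frac = 0.25,
                             label = "") {
  intensity <- as.numeric(intensity)
  L <- length(intensity)
  if (L < n_bins) stop("intensity trace shorter than n_bins")
  if (anyNA(intensity) || any(intensity < 0)) {
    stop("intensities must be non-negative and non-missing")
  }
  bin <- ceiling(seq_len(L) * n_bins / L)
  means <- as.numeric(tapply(intensity, factor(bin, levels = seq_len(n_bins)),
                             mean))
  mx <- max(means)
  vals <- as.numeric(means > threshold_frac * mx & mx > 0)
  out <- axis_profile(vals, "binary", label, n_bins = n_bins)
  attr(out, "domains") <- profile_domains(out)
  out
}

#' Read / write axis-profile tables
#'
#' Profile tables are TSV files without a header: column 1 is the profile
#' label, columns 2..(n_bins+1) the bin values, anterior first.
#'
#' @param path File path.
#' @param kind Profile kind to assign on read.
#' @param n_bins Number of bins (default 100).
#' @return `read_profiles()`: a named list of [axis_profile()] objects.
#' @export
read_profiles <- function(path, kind = c("continuous", "binary"),
                          n_bins = 100L) {
  kind <- match.arg(kind)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) != n_bins + 1L) {
    stop("expected ", n_bins + 1L, " columns (label + bins), got ", ncol(tab))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    axis_profile(as.numeric(tab[i, -1]), kind, tab[i, 1], n_bins = n_bins)
  })
  names(out) <- tab[[1]]
  out
}

#' @rdname read_profiles
#' @param profiles Named list of [axis_profile()] objects (or one profile).
#' @export
write_profiles <- function(profiles, path) {
  if (is_axis_profile(profiles)) profiles <- list(profiles)
  rows <- vapply(profiles, function(p) {
    paste(c(p$label, format(p$values, digits = 15, trim = TRUE,
                            scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
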