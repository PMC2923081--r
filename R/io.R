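#' Read and write FASTA sequence files
#'
#' Sequences are read with [Biostrings::readBStringSet()], uppercased and
#' validated against the DNA alphabet `{A, C, G, T, N}`. Record order is
#' preserved.
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector of uppercase sequences,
#'   one element per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal character in FASTA record '", names(seqs)[bad][1],
         "' (only A,C,G,T,N allowed)")
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("sequences must be named")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              format = "fasta", width = 70L)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' Parses the tree with [ape::read.tree()] and checks that every branch has
#' a finite non-negative length, as required by Brownian-motion averaging.
#'
#' @param path Newick file with a single tree.
#' @param text Newick string, as an alternative to `path`.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick tree")
  if (inherits(tr, "multiPhylo")) stop("expected a single Newick tree")
  validate_tree(tr)
  tr
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 leaves")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    stop("every branch must carry a branch length")
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  invisible(tree)
}

#' Construct a motif model (position weight matrix with background)
#'
#' @param freq 4 x width matrix of column frequencies, rows in order
#'   A, C, G, T; every column must sum to 1.
#' @param background Length-4 vector of background nucleotide frequencies
#'   (A, C, G, T), summing to 1.
#' @param pseudocount Pseudocount that was applied when the matrix was
#'   derived from counts (stored for provenance).
#' @param name Motif / TF name.
#' @return An object of class `motif_model` with fields `width`, `freq`,
#'   `background`, `pseudocount`, `name`.
#' @export
motif_model <- function(freq, background = rep(0.25, 4), pseudocount = 0,
                        name = "") {
  freq <- as.matrix(freq)
  if (nrow(freq) != 4) stop("frequency matrix must have 4 rows (A,C,G,T)")
  if (any(freq < 0)) stop("frequency matrix entries must be non-negative")
  cs <- colSums(freq)
  if (any(abs(cs - 1) > 1e-9)) stop("every PWM column must sum to 1")
  background <- as.numeric(background)
  if (length(background) != 4 || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 non-negative frequencies summing to 1")
  }
  rownames(freq) <- c("A", "C", "G", "T")
  structure(list(width = ncol(freq), freq = freq, background = background,
                 pseudocount = pseudocount, name = as.character(name)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s, width %d\n", x$name, x$width))
  print(round(x$freq, 3))
  invisible(x)
}

#' Load a motif from a JASPAR-like 4-row text file
#'
#' The file holds 4 rows of numbers (A, C, G, T), optionally prefixed by the
#' base letter and wrapped in brackets, optionally preceded by a `>` header
#' line. Counts (or frequencies) `x` are converted to column frequencies as
#' `(x + pseudocount) / (colsum + 4 * pseudocount)`; with `pseudocount = 0`
#' an already column-stochastic matrix is returned unchanged.
#'
#' @param path File path.
#' @param pseudocount Pseudocount added per cell before normalization
#'   (default 1).
#' @param background Background nucleotide frequencies (default uniform).
#' @return A [motif_model()].
#' @export
load_motif <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  lines <- readLines(path)
  name <- ""
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4) {
    stop("motif file must contain exactly 4 value rows (A,C,G,T), found ",
         length(lines))
  }
  rows <- lapply(lines, function(l) {
    l <- gsub("^\\s*[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(vapply(rows, length, 1L))) != 1) {
    stop("motif rows have unequal lengths")
  }
  m <- do.call(rbind, rows)
  if (anyNA(m)) stop("non-numeric entry in motif file")
  if (any(m < 0)) stop("negative entry in motif file")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  freq <- sweep(m + pseudocount, 2, colSums(m) + 4 * pseudocount, "/")
  motif_model(freq, background = background, pseudocount = pseudocount,
              name = name)
}

#' Genomic intervals (0-based half-open) and BED I/O
#'
#' Intervals are plain data frames with columns `seq_id`, `start`, `end`
#' (0-based half-open, `start < end`) and `strand` (`+`, `-` or `.`),
#' matching BED coordinate conventions.
#'
#' @param seq_id,start,end,strand Interval fields (vectorized).
#' @return A validated interval data frame.
#' @export
genomic_interval <- function(seq_id, start, end, strand = ".") {
  d <- data.frame(seq_id = as.character(seq_id), start = as.integer(start),
                  end = as.integer(end), strand = as.character(strand),
                  stringsAsFactors = FALSE)
  if (any(d$start < 0) || any(d$start >= d$end)) {
    stop("intervals must satisfy 0 <= start < end")
  }
  if (!all(d$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  d
}

#' @rdname genomic_interval
#' @param path BED file path.
#' @export
read_bed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  strand <- if (ncol(tab) >= 6) tab[[6]] else "."
  genomic_interval(tab[[1]], tab[[2]], tab[[3]], strand)
}

#' @rdname genomic_interval
#' @param intervals Interval data frame (with optional `name`/`score`
#'   columns used for BED columns 4-5).
#' @export
write_bed <- function(intervals, path) {
  nm <- if ("name" %in% names(intervals)) intervals$name else "."
  sc <- if ("score" %in% names(intervals)) intervals$score else 0
  out <- data.frame(intervals$seq_id, intervals$start, intervals$end,
                    nm, sc, intervals$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
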