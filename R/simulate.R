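BASES <- c("A", "C", "G", "T")

#' Generate a random motif of given information content
#'
#' Each column places probability `1 - e` on a randomly chosen consensus
#' base and `e/3` on each other base, with `e` solved so that the per-column
#' information content (relative to the uniform background,
#' `2 + sum p log2 p` bits) equals `strength`. `strength = 0` gives the
#' uniform background; `strength = 2` a pure consensus motif.
#'
#' @param seed Integer seed.
#' @param width Motif width (>= 4).
#' @param strength Target information content per column, in bits
#'   (0 to 2; more than 2 bits per column is impossible for DNA).
#' @return A [motif_model()].
#' @export
make_motif <- function(seed, width, strength) {
  if (width < 4) stop("width must be >= 4")
  if (strength > 2) stop("strength cannot exceed 2 bits per column")
  if (strength < 0) stop("strength must be non-negative")
  ic <- function(e) {
    h <- 0
    if (e < 1) h <- h + (1 - e) * log2(1 - e)
    if (e > 0) h <- h + e * log2(e / 3)
    2 + h
  }
  e <- if (strength >= 2) 0
       else if (strength <= 0) 0.75
       else uniroot(function(x) ic(x) - strength, c(1e-12, 0.75),
                    tol = 1e-12)$root
  withr::local_seed(seed)
  consensus <- sample(4, width, replace = TRUE)
  freq <- matrix(e / 3, 4, width)
  for (j in seq_len(width)) freq[consensus[j], j] <- 1 - e
  motif_model(freq, name = sprintf("motif_w%d_ic%.2g", width, strength))
}

sample_site <- function(motif) {
  paste(vapply(seq_len(motif$width), function(j) {
    sample(BASES, 1, prob = motif$freq[, j])
  }, character(1)), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Generate a locus with planted CRMs
#'
#' Draws a background sequence of the stated composition and plants motif
#' sites (sampled from each TF's PWM, random strand) at random
#' non-overlapping positions inside the designated CRM intervals.
#'
#' @param seed Integer seed.
#' @param length Locus length in bp.
#' @param gc GC fraction of the background (default 0.4).
#' @param plants Data frame with columns `start`, `end` (0-based half-open
#'   CRM intervals inside the locus); may have zero rows. Overlapping plants
#'   are an error.
#' @param motifs Named list of [motif_model()]s.
#' @param site_counts Plant x TF matrix (or NULL) of site counts to plant.
#' @param compute_scores Also score each plant with every motif
#'   ([crm_motif_score()]) and return the true S matrix (default `TRUE`)?
#' @return List: `sequence`, `plants` (interval data frame with `name`),
#'   `sites` (placement bookkeeping), `S` (plant x TF score matrix or NULL).
#' @export
make_locus <- function(seed, length, gc = 0.4, plants = NULL, motifs = list(),
                       site_counts = NULL, compute_scores = TRUE) {
  withr::local_seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq_chars <- sample(BASES, length, replace = TRUE, prob = probs)

  if (is.null(plants)) plants <- data.frame(start = integer(), end = integer())
  if (nrow(plants) > 1) {
    o <- order(plants$start)
    if (any(plants$start[o][-1] < plants$end[o][-nrow(plants)])) {
      stop("planted CRM intervals overlap")
    }
  }
  if (nrow(plants) && any(plants$end > length)) {
    stop("planted CRMs must fit inside the locus")
  }
  sites <- list()
  if (!is.null(site_counts) && nrow(plants)) {
    for (pl in seq_len(nrow(plants))) {
      occupied <- logical(plants$end[pl] - plants$start[pl])
      for (tf in colnames(site_counts)) {
        k <- site_counts[pl, tf]
        if (k == 0) next
        motif <- motifs[[tf]]
        if (is.null(motif)) stop("no motif supplied for TF ", tf)
        w <- motif$width
        placed <- 0
        tries <- 0
        while (placed < k) {
          tries <- tries + 1
          if (tries > 10000) stop("cannot place sites without overlap")
          off <- sample(length(occupied) - w + 1, 1)
          if (any(occupied[off:(off + w - 1)])) next
          occupied[off:(off + w - 1)] <- TRUE
          site <- sample_site(motif)
          strand <- sample(c("+", "-"), 1)
          if (strand == "-") site <- revcomp(site)
          pos <- plants$start[pl] + off  # 1-based locus coordinate
          seq_chars[pos:(pos + w - 1)] <- strsplit(site, "")[[1]]
          sites[[length(sites) + 1]] <- data.frame(
            plant = pl, tf = tf, start = pos - 1L, end = pos - 1L + w,
            strand = strand, stringsAsFactors = FALSE)
          placed <- placed + 1
        }
      }
    }
  }
  sequence <- paste(seq_chars, collapse = "")
  plant_iv <- if (nrow(plants)) {
    iv <- genomic_interval("locus", plants$start, plants$end)
    iv$name <- sprintf("plant_%d", seq_len(nrow(plants)))
    iv
  } else NULL
  S <- NULL
  if (compute_scores && nrow(plants) && base::length(motifs)) {
    S <- matrix(NA_real_, nrow(plants), base::length(motifs),
                dimnames = list(plant_iv$name, names(motifs)))
    for (pl in seq_len(nrow(plants))) {
      crm_seq <- substr(sequence, plants$start[pl] + 1, plants$end[pl])
      S[pl, ] <- vapply(names(motifs), function(tf) {
        crm_motif_score(crm_seq, motifs[[tf]])
      }, numeric(1))
    }
  }
  list(sequence = sequence, plants = plant_iv,
       sites = if (base::length(sites)) do.call(rbind, sites) else NULL,
       S = S)
}

#' Generate TF concentration profiles of standard shapes
#'
#' Supported shapes emulate the classic anterior-posterior factor profiles:
#' `"anterior"` (strictly decreasing gradient), `"posterior"` (strictly
#' increasing), `list("stripe", lo, hi)` (an interior expression stripe with
#' support exactly on bins `lo..hi`), `"terminal_high"` (high at both poles)
#' and `"terminal_low"` (its exact per-bin complement, so the pair sums
#' to 1).
#'
#' @param shapes Named list: TF name -> shape (a string, or
#'   `list("stripe", lo, hi)`).
#' @param n_bins Number of axis bins (default 100).
#' @return Named list of continuous [axis_profile()]s.
#' @export
make_concentrations <- function(shapes, n_bins = 100L) {
  b <- seq_len(n_bins)
  one <- function(shape, name) {
    if (is.list(shape) || length(shape) > 1) {
      type <- shape[[1]]
      if (type != "stripe") stop("unknown concentration shape: ", type)
      lo <- as.numeric(shape[[2]]); hi <- as.numeric(shape[[3]])
      if (lo < 1 || hi > n_bins || lo >= hi) stop("bad stripe bounds")
      v <- rep(0, n_bins)
      v[lo:hi] <- sin(pi * (b[lo:hi] - lo + 1) / (hi - lo + 2))^2
      return(axis_profile(v, "continuous", name, n_bins))
    }
    v <- switch(shape,
      anterior = exp(-3 * (b - 1) / (n_bins - 1)),
      posterior = exp(-3 * (n_bins - b) / (n_bins - 1)),
      terminal_high = pmax(exp(-(b - 1) / 8), exp(-(n_bins - b) / 8)),
      terminal_low = 1 - pmax(exp(-(b - 1) / 8), exp(-(n_bins - b) / 8)),
      stop("unknown concentration shape: ", shape))
    axis_profile(v, "continuous", name, n_bins)
  }
  out <- lapply(names(shapes), function(nm) one(shapes[[nm]], nm))
  setNames(out, names(shapes))
}

#' Simulate binary expression targets from the forward model
#'
#' Evaluates the logistic model with the supplied true weights and
#' baselines, thresholds the continuous prediction at 0.5 (values >= 0.5
#' become 1) to get clean binary targets, and then applies independent
#' per-bin flip noise.
#'
#' @param S CRM x TF motif-score matrix.
#' @param concentrations Named list of continuous [axis_profile()]s.
#' @param weights Named numeric vector of true term weights (second-order
#'   terms named `"<tf>^2"`).
#' @param baselines Named numeric vector (per CRM) or single value recycled.
#' @param covariate_spec Covariate spec; default first-order terms for all
#'   TFs in `S`.
#' @param noise Per-bin flip probability on the binary targets (default 0).
#' @param seed Integer seed (used only for the noise).
#' @return List of named lists of [axis_profile()]s: `clean`, `noisy`,
#'   `continuous`.
#' @export
simulate_expression <- function(S, concentrations, weights, baselines,
                                covariate_spec = NULL, noise = 0, seed = 1L) {
  C <- conc_matrix(concentrations)
  spec <- validate_covariate_spec(covariate_spec, colnames(S))
  crms <- rownames(S)
  if (length(baselines) == 1) {
    baselines <- setNames(rep(baselines, length(crms)), crms)
  }
  model <- regression_model(weights[term_labels(spec)], baselines, spec)
  withr::local_seed(seed)
  cont <- clean <- noisy <- list()
  for (l in crms) {
    pred <- predict_expression(model, row_of(S, l), C, crm = l)
    cv <- as.numeric(pred$values >= 0.5)
    nv <- cv
    if (noise > 0) {
      flip <- runif(length(nv)) < noise
      nv[flip] <- 1 - nv[flip]
    }
    cont[[l]] <- pred
    clean[[l]] <- axis_profile(cv, "binary", l, ncol(C))
    noisy[[l]] <- axis_profile(nv, "binary", l, ncol(C))
  }
  list(clean = clean, noisy = noisy, continuous = cont)
}

#' Evolve orthologous sequences along a phylogeny
#'
#' Starting from an ancestral sequence at the root, substitutes sites
#' independently along each branch under the Jukes-Cantor model: on a branch
#' of length `t`, each site changes with probability
#' `3/4 (1 - exp(-4 rate t / 3))`, uniformly to one of the three other
#' bases. No indels occur, so windows correspond positionally across
#' species.
#'
#' @param tree Rooted `"phylo"` tree with branch lengths.
#' @param ancestral Ancestral DNA sequence (root state).
#' @param rate Substitution rate per unit branch length (>= 0).
#' @param seed Integer seed.
#' @param window,shift Window tiling used for the orthology map
#'   (defaults 500/250).
#' @return List: `sequences` (named by tip label), `orthology` (data frame
#'   `window`, `species`, `ortholog`; positional, every species maps window
#'   i to window i).
#' @export
evolve_orthologs <- function(tree, ancestral, rate, seed = 1L, window = 500L,
                             shift = 250L) {
  validate_tree(tree)
  if (rate < 0) stop("rate must be non-negative")
  withr::local_seed(seed)
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  seqs <- vector("list", n_node)
  root <- ntip + 1L
  seqs[[root]] <- encode_sequence(ancestral)
  po <- ape::reorder.phylo(tree, "postorder")
  for (idx in rev(seq_len(nrow(po$edge)))) {   # parent before child
    p <- po$edge[idx, 1]; v <- po$edge[idx, 2]
    t_b <- po$edge.length[idx]
    s <- seqs[[p]]
    psub <- 0.75 * (1 - exp(-4 * rate * t_b / 3))
    hit <- which(runif(length(s)) < psub & s != 0L)
    if (length(hit)) {
      s[hit] <- vapply(s[hit], function(cur) {
        sample(setdiff(1:4, cur), 1)
      }, integer(1))
    }
    seqs[[v]] <- s
  }
  decode <- function(cs) paste(c("N", BASES)[cs + 1L], collapse = "")
  sequences <- setNames(
    vapply(seq_len(ntip), function(i) decode(seqs[[i]]), character(1)),
    tree$tip.label)
  n_win <- max(0L, (nchar(ancestral) - window) %/% shift + 1L)
  orthology <- do.call(rbind, lapply(tree$tip.label, function(sp) {
    data.frame(window = seq_len(n_win), species = sp,
               ortholog = seq_len(n_win), stringsAsFactors = FALSE)
  }))
  list(sequences = sequences, orthology = orthology)
}
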