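# Shared synthetic fixtures and independent oracles used across the suite.

AP_TFS <- c("BCD", "CAD", "FKH", "HB", "KR", "KNI", "GT", "TLL", "HKB", "CIC")

ap_shapes <- function() {
  list(BCD = "anterior", CAD = "posterior", FKH = "terminal_high",
       HB = "anterior", KR = list("stripe", 40, 60),
       KNI = list("stripe", 60, 70), GT = list("stripe", 20, 40),
       TLL = "terminal_high", HKB = "terminal_high", CIC = "terminal_low")
}

ap_true_weights <- function() {
  setNames(c(1.2, 1.0, 0.8, -1.0, -1.5, -1.2, -0.9, -1.1, -0.8, -1.3), AP_TFS)
}

# Standard A/P training fixture: n_crm CRMs x 10 TFs x 100 bins.
# Score rows are redrawn until the implied clean pattern is non-degenerate
# (5%-95% expressed bins), mirroring the patterned CRMs of a real training
# set.
ap_fixture <- function(seed, n_crm = 46, noise = 0) {
  conc <- make_concentrations(ap_shapes())
  w_true <- ap_true_weights()
  C <- do.call(rbind, lapply(conc, function(p) p$values))
  S <- matrix(NA_real_, n_crm, 10,
              dimnames = list(sprintf("crm%02d", seq_len(n_crm)), AP_TFS))
  alpha <- setNames(numeric(n_crm), rownames(S))
  withr::with_seed(seed, {
    for (l in seq_len(n_crm)) {
      repeat {
        s <- runif(10, 0, 4) * rbinom(10, 1, 0.6)
        a <- runif(1, -2, 0)
        cl <- as.numeric(plogis(a + colSums((C * s) * w_true)) >= 0.5)
        if (mean(cl) >= 0.05 && mean(cl) <= 0.95) {
          S[l, ] <- s
          alpha[l] <- a
          break
        }
      }
    }
  })
  sim <- simulate_expression(S, conc, w_true, alpha, noise = noise,
                             seed = seed + 1)
  list(S = S, conc = conc, w_true = w_true, alpha = alpha, sim = sim)
}

# Planted 3-TF x 6-CRM regulatory network: two activators with opposed
# gradients and one central-stripe repressor placed where activation is on,
# so every wired edge has a visible consequence on the pattern.
net_fixture <- function(seed = 1, noise = 0.05) {
  tfs <- c("A1", "A2", "R1")
  conc <- make_concentrations(list(A1 = "anterior", A2 = "posterior",
                                   R1 = list("stripe", 25, 75)))
  w_true <- c(A1 = 1.2, A2 = 1.1, R1 = -2.0)
  wiring <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 1),
                  c(0, 1, 1), c(1, 1, 0), c(1, 1, 1))
  dimnames(wiring) <- list(sprintf("crm%d", 1:6), tfs)
  S <- withr::with_seed(seed, wiring * matrix(runif(18, 3, 5), 6, 3))
  alpha <- setNames(rep(-1, 6), rownames(S))
  sim <- simulate_expression(S, conc, w_true, alpha, noise = noise,
                             seed = seed + 1)
  list(tfs = tfs, conc = conc, w_true = w_true, wiring = wiring, S = S,
       alpha = alpha, sim = sim)
}

# Discovery fixture: anterior gene pattern driven by a planted CRM carrying
# BCD sites, scanned with a 3-TF model.
disc_fixture <- function() {
  tfs <- c("BCD", "CAD", "KR")
  motifs <- list(BCD = make_motif(101, 8, 1.5), CAD = make_motif(102, 8, 1.5),
                 KR = make_motif(103, 8, 1.5))
  for (tf in tfs) motifs[[tf]]$name <- tf
  conc <- make_concentrations(list(BCD = "anterior", CAD = "posterior",
                                   KR = list("stripe", 40, 60)))
  model <- regression_model(
    c(BCD = 0.6, CAD = 0.6, KR = -0.8),
    baselines = c(train1 = -3, train2 = -3),
    covariate_spec = data.frame(tf = tfs, order = 1L))
  gene <- axis_profile(rep(c(1, 0), c(30, 70)), "binary", "gene")
  list(tfs = tfs, motifs = motifs, conc = conc, model = model, gene = gene)
}

disc_locus <- function(seed, fx, plant = TRUE, length = 22000) {
  sc <- matrix(0L, 1, 3, dimnames = list(NULL, fx$tfs))
  sc[1, "BCD"] <- 8L
  make_locus(seed, length, gc = 0.4,
             plants = if (plant) data.frame(start = 10000, end = 11000),
             motifs = fx$motifs, site_counts = if (plant) sc,
             compute_scores = FALSE)
}

# z-scores of scanned windows against a background scan, per TF
scan_z <- function(scan, null_scan, tfs) {
  sapply(tfs, function(tf) {
    ns <- null_scan[[paste0("S_", tf)]]
    mu <- mean(ns)
    sg <- sqrt(mean((ns - mu)^2))
    (scan[[paste0("S_", tf)]] - mu) / sg
  })
}

# --- independent oracles ----------------------------------------------------

# Exhaustive enumeration of all legal non-overlapping site placements (both
# strands); the independent likelihood oracle for the HMM forward score.
enum_llr <- function(seq, motif, q) {
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  W <- motif$width
  L <- length(codes)
  bg <- motif$background
  f <- motif$freq
  site_p <- function(pos, strand) {
    p <- 1
    for (w in seq_len(W)) {
      c0 <- codes[pos + w - 1]
      p <- p * if (strand == "+") f[c0, w] else f[5 - c0, W + 1 - w]
    }
    p
  }
  total <- 0
  rec <- function(j, acc) {
    if (j > L) {
      total <<- total + acc
      return(invisible())
    }
    rec(j + 1, acc * (1 - q) * bg[codes[j]])
    if (j + W - 1 <= L) {
      rec(j + W, acc * q / 2 * site_p(j, "+"))
      rec(j + W, acc * q / 2 * site_p(j, "-"))
    }
  }
  rec(1, 1)
  unname(log(total) - sum(log(bg[codes])))
}

# direct Bernoulli log-likelihood of a model on a dataset (AIC oracle)
direct_loglik <- function(model, S, conc, targets) {
  ll <- 0
  for (l in rownames(S)) {
    mu <- predict_expression(model, S[l, ], conc, crm = l)$values
    y <- targets[[l]]$values
    ll <- ll + sum(ifelse(y == 1, log(pmax(mu, 1e-12)),
                          log(pmax(1 - mu, 1e-12))))
  }
  ll
}

# penalized-likelihood oracle: generic quasi-Newton fit of the same ridge
# objective, independent of the IWLS code path
lbfgs_loglik <- function(S, conc, targets, lambda = 1e-6) {
  C <- do.call(rbind, lapply(conc, function(p) p$values))
  n_crm <- nrow(S)
  X <- do.call(rbind, lapply(seq_len(n_crm), function(l) t(C * S[l, ])))
  Xf <- cbind(X, kronecker(diag(n_crm), rep(1, ncol(C))))
  y <- unlist(lapply(rownames(S), function(l) targets[[l]]$values))
  lse <- function(eta) ifelse(eta > 30, eta + log1p(exp(-eta)),
                              log1p(exp(eta)))
  nll <- function(b) {
    eta <- as.numeric(Xf %*% b)
    -sum(y * eta - lse(eta)) + lambda * sum(b^2) / 2
  }
  gr <- function(b) {
    mu <- plogis(as.numeric(Xf %*% b))
    -as.numeric(crossprod(Xf, y - mu)) + lambda * b
  }
  o <- optim(rep(0, ncol(Xf)), nll, gr, method = "L-BFGS-B",
             control = list(maxit = 20000, factr = 1))
  mu <- plogis(as.numeric(Xf %*% o$par))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

revcomp_seq <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
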