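test_that("dense epsilon rule matches hand-worked splits and conserves", {
  # proportional split, zero bias
  r <- lrp_dense(5, matrix(c(1, 1), 2, 1), 0, c(2, 3))
  expect_equal(r$r_in, c(2, 3), tolerance = 1e-8)
  expect_equal(r$bias_absorbed, 0, tolerance = 1e-8)
  # unit bias takes exactly its share
  r <- lrp_dense(6, matrix(c(1, 1), 2, 1), 1, c(2, 3))
  expect_equal(r$r_in, c(2, 3), tolerance = 1e-8)
  expect_equal(r$bias_absorbed, 1, tolerance = 1e-8)
  # conservation on seeded random layers
  set.seed(31)
  for (i in 1:100) {
    din <- sample(3:20, 1); dout <- sample(2:10, 1)
    W <- matrix(rnorm(din * dout), din, dout)
    b <- rnorm(dout); x <- rnorm(din); rout <- rnorm(dout)
    res <- lrp_dense(rout, W, b, x)
    expect_lt(abs(sum(res$r_in) + res$bias_absorbed - sum(rout)) /
                max(1, abs(sum(rout))), 1e-6)
  }
})

test_that("conv rule equals the unfolded-dense brute force for k <= 5, n <= 12", {
  unfold <- function(K, b, Np, d, k) {
    nw <- Np - k + 1L; Fk <- ncol(K)
    bigW <- matrix(0, Np * d, nw * Fk); bigb <- numeric(nw * Fk)
    for (p in seq_len(nw)) for (f in seq_len(Fk)) {
      col <- (p - 1L) * Fk + f
      bigW[((p - 1L) * d + 1L):((p + k - 1L) * d), col] <- K[, f]
      bigb[col] <- b[f]
    }
    list(W = bigW, b = bigb)
  }
  set.seed(13)
  for (k in 1:5) {
    for (Np in unique(pmin(12L, c(k, k + 2L, 12L)))) {
      d <- sample(2:4, 1); Fk <- sample(2:5, 1)
      Z <- matrix(rnorm(Np * d), Np, d)
      K <- matrix(rnorm(k * d * Fk), k * d, Fk)
      b <- rnorm(Fk)
      rmap <- matrix(rnorm((Np - k + 1) * Fk), Np - k + 1, Fk)
      res <- lrp_conv(rmap, K, b, Z)
      uf <- unfold(K, b, Np, d, k)
      ref <- lrp_dense(as.vector(t(rmap)), uf$W, uf$b, as.vector(t(Z)))
      expect_equal(res$r_in, matrix(ref$r_in, Np, d, byrow = TRUE),
                   tolerance = 1e-6)
      expect_equal(res$bias_absorbed, ref$bias_absorbed, tolerance = 1e-6)
      # conservation, exact when bias is zero
      res0 <- lrp_conv(rmap, K, numeric(Fk), Z, eps = 1e-12)
      expect_lt(abs(sum(res0$r_in) - sum(rmap)) / max(1, abs(sum(rmap))),
                1e-6)
    }
  }
  # kernel size 1 reduces exactly to the dense rule per window
  Z <- matrix(rnorm(8), 4, 2); K1 <- matrix(rnorm(6), 2, 3); b1 <- rnorm(3)
  r1 <- matrix(rnorm(12), 4, 3)
  cv <- lrp_conv(r1, K1, b1, Z)
  dn <- t(vapply(1:4, function(p) lrp_dense(r1[p, ], K1, b1, Z[p, ])$r_in,
                 numeric(2)))
  expect_equal(cv$r_in, dn, tolerance = 1e-10)
})

test_that("max-pool inversion is winner-take-all with first-index ties", {
  expect_equal(as.vector(lrp_maxpool(1, matrix(c(0.2, 0.9, 0.1), 3, 1))),
               c(0, 1, 0))
  tie <- lrp_maxpool(2, matrix(c(0.5, 0.5, 0.1), 3, 1))
  expect_equal(as.vector(tie), c(2, 0, 0))  # lowest index wins
  set.seed(8)
  for (i in 1:25) {
    M <- matrix(rnorm(24), 6, 4); r <- rnorm(4)
    expect_equal(colSums(lrp_maxpool(r, M)), r)  # exact conservation
  }
})

test_that("highway gate follows signal-take-all", {
  h1 <- lrp_highway(1, 1 - 1e-12, 2, 5)
  expect_equal(h1$r_transform, 1, tolerance = 1e-9)
  expect_equal(h1$r_carry, 0, tolerance = 1e-9)
  h0 <- lrp_highway(1, 1e-12, 2, 5)
  expect_equal(h0$r_carry, 1, tolerance = 1e-9)
  hs <- lrp_highway(1, 0.7, 2, 1)  # contributions 1.4 vs 0.3
  expect_equal(hs$r_transform, 14 / 17, tolerance = 1e-8)
  expect_equal(hs$r_carry, 3 / 17, tolerance = 1e-8)
  # vector form conserves exactly
  set.seed(9)
  g <- runif(20); h <- rnorm(20); x <- rnorm(20); r <- rnorm(20)
  sp <- lrp_highway(r, g, h, x)
  expect_equal(sp$r_transform + sp$r_carry, r, tolerance = 1e-6)
})

test_that("propagation ledger keeps the bookkeeping identities", {
  qm <- tiny_qsar()
  for (s in small_library()[1:5]) {
    p <- propagate_relevance(qm, s)
    led <- p$ledger
    mid <- led[!led$layer %in% c("Result", "Total"), ]
    expect_equal(mid$delta, mid$r_upper - mid$r_lower)
    nz <- mid$r_upper != 0
    expect_equal(mid$bias_pct[nz], 100 * mid$delta[nz] / mid$r_upper[nz])
    # the Total delta equals the sum of every layer's absorbed bias
    tot <- led[led$layer == "Total", ]
    expect_equal(tot$delta, sum(mid$delta), tolerance = 1e-8)
    # conv rows hand off exactly what the de-pooled dense produced
    expect_equal(sum(mid$r_upper[grepl("^Conv", mid$layer)]),
                 led$r_lower[led$layer == "DeMaxPool"], tolerance = 1e-8)
    expect_equal(length(p$per_position), nchar(s) + 2L)
    expect_equal(sum(p$per_position), tot$r_lower, tolerance = 1e-10)
  }
})

test_that("a bias-free head dissipates (almost) nothing", {
  qm <- tiny_qsar()
  qm0 <- qm
  for (nm in grep("\\.b[th]?$", names(qm0$head$params), value = TRUE))
    qm0$head$params[[nm]] <- qm0$head$params[[nm]] * 0
  p <- propagate_relevance(qm0, small_library()[3])
  tot <- p$ledger[p$ledger$layer == "Total", ]
  expect_lt(abs(tot$bias_pct), 1e-6)
})

test_that("applicability flag trips below half-propagated relevance", {
  ok <- relevance_ledger(c("Result", "Total"), c(1, 1), c(NA, 0.754))
  expect_equal(applicability_flag(ok), "ok")
  warn <- relevance_ledger(c("Result", "Total"), c(1, 1), c(NA, 0.40))
  expect_equal(applicability_flag(warn), "warning")
  edge <- relevance_ledger(c("Result", "Total"), c(1, 1), c(NA, 0.50))
  expect_equal(applicability_flag(edge), "ok")  # boundary convention
})

test_that("characters partition onto atoms by the folding rules", {
  m <- map_chars_to_atoms("Brc1ccccc1")
  expect_equal(m$spans[[1]], 1:2)            # Br owns both letters
  expect_equal(m$elements[1], "Br")
  expect_equal(m$spans[[2]], 3:4)            # ring digit folds to c
  expect_equal(length(m$spans), 7L)

  m2 <- map_chars_to_atoms("[O-]")
  expect_equal(length(m2$spans), 1L)
  expect_equal(m2$spans[[1]], 1:4)
  expect_equal(m2$elements, "O")

  m3 <- map_chars_to_atoms("CC(=O)O")
  expect_equal(length(m3$spans), 4L)
  expect_equal(m3$spans[[2]], c(2, 3, 4))    # '(' and '=' fold back to the C
  expect_equal(m3$spans[[3]], c(5, 6))       # O owns itself and ')'

  # partition property over toy and drug-like strings
  for (s in c(small_library()[1:30], drug_smiles)) {
    mm <- map_chars_to_atoms(s)
    all_idx <- sort(c(unlist(mm$spans), mm$prefix))
    expect_equal(all_idx, seq_len(nchar(s)))
  }
})

test_that("atom attribution averages over one rooted SMILES per heavy atom", {
  qm <- tiny_qsar()
  o <- grammar_oracle()
  s <- "CC(Cl)C(N)O"
  att <- atom_attribution(qm, s, o)
  expect_equal(att$n_rooted, 6L)
  expect_length(att$contributions, 6L)
  expect_true(all(is.finite(att$contributions)))
  expect_equal(att$elements, c("C", "C", "Cl", "C", "N", "O"))
  expect_true(is.finite(att$mean_bias_pct))

  # benzene through the chemistry toolkit: 6 rooted strings, 6 atoms
  o_tk <- rdkit_oracle()
  att_b <- atom_attribution(qm, "c1ccccc1", o_tk)
  expect_equal(att_b$n_rooted, 6L)
  # the bromo-nitrobenzene workflow uses 10 rooted SMILES (10 heavy atoms)
  expect_equal(o_tk$heavy_atom_count("O=[N+]([O-])c1ccc(Br)cc1"), 10L)
})
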