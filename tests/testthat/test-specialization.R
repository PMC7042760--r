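test_that("d' matches hand-computed Kullback-Leibler reference cases", {
  # perfectly complementary 2x2: each pollinator fully specialized
  perfect <- species_dprime(quant_network(diag(2) * 2), "pollinator")
  expect_equal(perfect$d, rep(log(2), 2))
  expect_equal(perfect$d_min, c(0, 0))
  expect_equal(perfect$d_prime, c(1, 1))

  # uniform 2x2: observed equals proportional allocation
  flat <- species_dprime(quant_network(matrix(1, 2, 2)), "pollinator")
  expect_equal(flat$d, flat$d_min)
  expect_equal(flat$d_prime, c(0, 0))

  # skewed 2x2: the integer optimum (3,1) equals the observed use
  skew <- species_dprime(
    quant_network(matrix(c(3, 1, 1, 1), 2, 2)), "pollinator"
  )
  expect_equal(skew$d[1], 0.0164, tolerance = 1e-2)
  expect_equal(skew$d[1], skew$d_min[1])
  expect_equal(skew$d_max[1], log(6 / 4))
  expect_equal(skew$d_prime[1], 0)
})

test_that("reference extremes equal exhaustive optima on small matrices", {
  mats <- list(
    matrix(c(3, 1, 1, 1), 2, 2), matrix(c(2, 0, 0, 2), 2, 2),
    matrix(c(1, 2, 0, 1, 1, 1), 2, 3), matrix(c(2, 1, 1, 0, 0, 2), 2, 3)
  )
  for (a in mats) {
    r <- rowSums(a)
    c <- colSums(a)
    all_tabs <- enumerate_tables(r, c)
    ents <- vapply(all_tabs, entropy_oracle, numeric(1))
    h <- h2prime(quant_network(a))
    expect_equal(h$H2_max, max(ents), tolerance = 1e-10)
    expect_equal(h$H2_min, min(ents), tolerance = 1e-10)
    # d_min against exhaustive allocation enumeration, both levels
    for (level in c("pollinator", "plant")) {
      sc <- species_dprime(quant_network(a), level)
      mm <- if (level == "pollinator") a else t(a)
      q <- rowSums(mm) / sum(mm)
      for (j in seq_len(ncol(mm))) {
        A <- sum(mm[, j])
        best <- min(vapply(
          enumerate_allocations(A, length(q)),
          function(al) kl_oracle(al, q), numeric(1)
        ))
        expect_equal(sc$d_min[j], best, tolerance = 1e-10)
      }
    }
  }
})

test_that("H2' matches hand-computed entropy references", {
  h_perfect <- h2prime(quant_network(diag(2) * 2))
  expect_equal(h_perfect$H2, log(2))
  expect_equal(h_perfect$H2_max, log(4))
  expect_equal(h_perfect$H2_prime, 1)

  h_flat <- h2prime(quant_network(matrix(1, 2, 2)))
  expect_equal(h_flat$H2, h_flat$H2_max)
  expect_equal(h_flat$H2_prime, 0)

  h_skew <- h2prime(quant_network(matrix(c(3, 1, 1, 1), 2, 2)))
  expect_equal(h_skew$H2_min, 0.6365, tolerance = 1e-3)
  expect_equal(h_skew$H2_max, 1.2425, tolerance = 1e-3)
  expect_equal(h_skew$H2_prime, 0)

  degenerate <- h2prime(quant_network(matrix(c(2, 3), 1, 2)))
  expect_false(degenerate$computable)
  expect_true(is.na(degenerate$H2_prime))
})

test_that("indices respect bounds and matrix permutation invariance", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      a <- random_count_matrix(4, 5)
      net <- quant_network(a)
      perm <- unclass(net)[sample(4), sample(5)]
      pnet <- quant_network(perm)
      h <- h2prime(net)
      expect_true(h$H2_prime >= 0 && h$H2_prime <= 1)
      expect_equal(h$H2_prime, h2prime(pnet)$H2_prime, tolerance = 1e-9)
      expect_equal(wnodf(net), wnodf(pnet), tolerance = 1e-9)
      expect_equal(
        dependence_asymmetry(net), dependence_asymmetry(pnet),
        tolerance = 1e-12
      )
      sc <- species_dprime(net, "plant")
      expect_true(all(sc$d_prime >= 0 & sc$d_prime <= 1))
      sc_p <- species_dprime(pnet, "plant")
      expect_equal(
        sc$d_prime[order(sc$species)], sc_p$d_prime[order(sc_p$species)],
        tolerance = 1e-9
      )
      da <- dependence_asymmetry(net)
      expect_true(da >= -1 && da <= 1)
      expect_equal(
        dependence_asymmetry(quant_network(t(a))), -da,
        tolerance = 1e-12
      )
      w <- wnodf(net)
      expect_true(w >= 0 && w <= 100)
    }
  })
})

test_that("doubling every count preserves H2 and the d' ordering", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      a <- random_count_matrix(3, 4)
      net <- quant_network(a)
      net2 <- quant_network(a * 2)
      expect_equal(h2prime(net)$H2, h2prime(net2)$H2, tolerance = 1e-12)
      d1 <- species_dprime(net, "pollinator")$d_prime
      d2 <- species_dprime(net2, "pollinator")$d_prime
      # monotone association (reference tables shift under the k=2 scaling)
      if (sd(d1) > 0 && sd(d2) > 0) {
        expect_true(cor(d1, d2, method = "spearman") > 0.5)
      }
    }
  })
})

test_that("WNODF agrees with the definitional oracle and its tie rule", {
  expect_equal(wnodf(quant_network(matrix(c(5, 3, 2, 0), 2, 2))), 100)
  expect_equal(wnodf(quant_network(diag(2) + 0)), 0)
  withr::with_seed(11, {
    for (rep in 1:25) {
      a <- random_count_matrix(4, 4)
      expect_equal(wnodf(quant_network(a)), wnodf_oracle(a), tolerance = 1e-10)
    }
  })
})

test_that("dependence asymmetry reproduces its hand-computed link values", {
  expect_equal(dependence_asymmetry(quant_network(matrix(1, 2, 2))), 0)
  expect_equal(dependence_asymmetry(quant_network(matrix(c(1, 1), 1, 2))), 0.5)
})

test_that("community and species-mean summaries combine d' correctly", {
  one <- tibble::tibble(
    species = "x", level = "pollinator", d = 0, d_min = 0, d_max = 1,
    d_prime = 0.7, n_events = 3
  )
  cs <- community_dprime(one)
  expect_equal(cs$mean_dprime, 0.7)
  expect_true(is.na(cs$cv_dprime))

  two <- dplyr::bind_rows(one, dplyr::mutate(one, species = "y", d_prime = 0.5))
  two$d_prime <- c(0.5, 0.5)
  expect_equal(community_dprime(two)$cv_dprime, 0)

  wts <- dplyr::bind_rows(
    dplyr::mutate(one, d_prime = 1, n_events = 3),
    dplyr::mutate(one, species = "y", d_prime = 0, n_events = 1)
  )
  expect_equal(community_dprime(wts)$mean_dprime, 0.75)

  scores <- tibble::tibble(
    species = c(rep("a", 3), rep("b", 2)),
    d_prime = c(0.2, 0.4, 0.6, 0.9, 0.8)
  )
  sm <- species_mean_dprime(scores, min_obs = 3)
  expect_equal(sm$species, "a")
  expect_equal(sm$mean_dprime, 0.4)
})
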