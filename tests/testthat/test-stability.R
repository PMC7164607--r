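test_that("Cq-to-linear conversion matches the element-wise definition", {
  cqc <- matrix(24, 2, 5, dimnames = list(c("a", "b"), NULL))
  expect_true(all(cq_to_linear(cqc) == 1))

  cq1 <- matrix(c(20, 21), 1, 2, dimnames = list("g", NULL))
  expect_equal(unname(cq_to_linear(cq1, 2)[1, ]), c(1, 0.5))

  cq <- random_cq(4, 6, seed = 51)
  effs <- c(2, 1.9, 2.1, 1.8)
  q <- cq_to_linear(cq, effs)
  for (i in 1:4) {
    for (j in 1:6) {
      expect_equal(q[i, j], effs[i]^(min(cq[i, ]) - cq[i, j]))
    }
  }
  expect_equal(unname(apply(q, 1, max)), rep(1, 4))
  expect_error(cq_to_linear(cq, 1), "exceed 1")
})

test_that("delta-Ct stability equals the pairwise-SD oracle and its invariances", {
  # two genes offset by a constant: perfectly co-varying, both values 0
  base <- c(20, 21, 22, 23)
  cq2 <- rbind(a = base, b = base + 1.5)
  expect_equal(delta_ct_stability(cq2)$value, c(0, 0))

  cq <- random_cq(3, 4, seed = 52)
  got <- delta_ct_stability(cq)
  expect_equal(got$value, unname(oracle_delta_ct(cq)))

  # invariant under a per-sample shift applied to all genes
  shift <- rnorm(4)
  cq_s <- cq + matrix(shift, 3, 4, byrow = TRUE)
  expect_equal(delta_ct_stability(cq_s)$value, got$value)

  expect_error(delta_ct_stability(cq[1, , drop = FALSE]), ">= 2 genes")
})

test_that("BestKeeper dispersion has the documented forms and asymmetry", {
  cqc <- matrix(22, 1, 5, dimnames = list("c", NULL))
  expect_equal(bestkeeper_stability(cqc)$value, 0)

  cq19 <- matrix(c(19, 21), 1, 2, dimnames = list("g", NULL))
  expect_equal(bestkeeper_stability(cq19, "mad")$value, 1.0)
  expect_equal(bestkeeper_stability(cq19, "sd")$value, sqrt(2))

  cq <- random_cq(4, 6, seed = 53)
  # gene-wise constant shift leaves values unchanged
  cq_g <- cq
  cq_g[2, ] <- cq_g[2, ] + 3
  expect_equal(bestkeeper_stability(cq_g)$value, bestkeeper_stability(cq)$value)
  # but per-sample shifts change raw-Cq dispersion (documented asymmetry)
  cq_s <- cq + matrix(seq(0, 5, length.out = 6), 4, 6, byrow = TRUE)
  expect_false(isTRUE(all.equal(
    bestkeeper_stability(cq_s)$value, bestkeeper_stability(cq)$value
  )))
})

test_that("NormFinder residual model matches the explicit two-way oracle", {
  # additive gene + sample structure only: all residuals 0
  gene_eff <- c(0, 1, 2.5)
  samp_eff <- c(0, 0.4, -0.7, 1.1)
  cq_add <- 22 + outer(gene_eff, rep(1, 4)) + outer(rep(1, 3), samp_eff)
  rownames(cq_add) <- c("a", "b", "c")
  expect_equal(normfinder_stability(cq_add)$value, rep(0, 3), tolerance = 1e-12)

  cq <- random_cq(4, 6, seed = 54)
  y <- log2(cq_to_linear(cq, 2))
  r_or <- oracle_two_way_residuals(y)
  g <- 4
  want <- sqrt(g / (g - 1)) *
    apply(r_or, 1, function(z) sqrt(sum(z^2) / (length(z) - 1)))
  got <- normfinder_stability(cq)
  expect_equal(got$value, unname(want), tolerance = 1e-12)
  # no inflation variant is the plain residual SD
  expect_equal(
    normfinder_stability(cq, inflation = "none")$value,
    unname(want) / sqrt(g / (g - 1)),
    tolerance = 1e-12
  )

  # sample-effect absorption: per-sample shifts leave values unchanged
  cq_s <- cq + matrix(rnorm(6, 0, 2), 4, 6, byrow = TRUE)
  expect_equal(normfinder_stability(cq_s)$value, got$value, tolerance = 1e-10)

  expect_error(normfinder_stability(cq[1:2, ]), ">= 3 genes")
})

test_that("grouped NormFinder penalizes intergroup shifts and validates groups", {
  groups <- rep(c("fruit", "endocarp"), c(6, 4))
  cq <- random_cq(4, 10, seed = 55, sd = 0.1)
  # plant a strong group difference into gene 4
  cq_b <- cq
  cq_b[4, groups == "endocarp"] <- cq_b[4, groups == "endocarp"] + 3
  res <- normfinder_stability(cq_b, groups = groups)
  expect_identical(res$gene_id[which.max(res$value)], "g04")
  expect_identical(unname(res$rank[4]), 4)
  # decomposition attribute covers every group
  dec <- attr(res, "decomposition")
  expect_setequal(vapply(dec, `[[`, "", "group"), c("fruit", "endocarp"))

  expect_error(
    normfinder_stability(cq, groups = rep(c("a", "b"), c(9, 1))),
    "fewer than 2"
  )
  expect_error(normfinder_stability(cq, groups = c("a", "b")), "one label")
})

test_that("geNorm M values, elimination order and ranks match brute-force recomputation", {
  # proportional genes have zero pairwise variation
  q2 <- rbind(a = c(1, 2, 4, 8), b = 3 * c(1, 2, 4, 8), c = c(1, 1, 2, 1))
  gn2 <- genorm_stability(q2)
  expect_equal(
    sd(log2(q2["a", ] / q2["b", ])), 0
  )

  for (seed in c(61, 62, 63)) {
    for (g in 4:6) {
      cq <- random_cq(g, 5, seed = seed + g, sd = 0.8)
      q <- cq_to_linear(cq, 2)
      got <- genorm_stability(q)
      want <- oracle_genorm_elimination(q)
      expect_identical(attr(got, "elimination_order"), want$eliminated)
      expect_equal(
        setNames(got$m_value, got$gene_id),
        want$m_last[got$gene_id]
      )
      # reverse elimination order with the survivors tied at 1.5
      surv <- got$gene_id[got$elimination_round == 0]
      expect_identical(sort(surv), sort(want$survivors))
      expect_equal(got$rank[got$elimination_round == 0], c(1.5, 1.5))
      first_out <- want$eliminated[1]
      expect_equal(got$rank[got$gene_id == first_out], g)
      # final-pair M values equal their mutual pairwise variation
      expect_equal(
        got$m_value[got$elimination_round == 0],
        rep(sd(log2(q[surv[1], ] / q[surv[2], ])), 2)
      )
    }
  }

  # split tie mode assigns ranks 1 and 2
  q <- cq_to_linear(random_cq(4, 5, seed = 65), 2)
  gs <- genorm_stability(q, tie_mode = "split")
  expect_setequal(gs$rank[gs$elimination_round == 0], c(1, 2))
  expect_error(genorm_stability(q * 0), "> 0")
})

test_that("first-round geNorm M equals delta-Ct stability at perfect doubling", {
  for (seed in 1:20) {
    cq <- random_cq(5, 8, seed = 700 + seed, sd = 0.6)
    m1 <- oracle_genorm_m(cq_to_linear(cq, 2))
    dct <- delta_ct_stability(cq)$value
    expect_equal(unname(m1), dct, tolerance = 1e-10)
  }
})

test_that("pairwise variation V(k/k+1) matches the direct normalization-factor formula", {
  qc <- matrix(1, 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  qc <- qc * rep(c(1, 2, 0.5, 1, 3), 4) # identical per-sample profiles
  for (k in 2:4) {
    expect_equal(genorm_pairwise_variation(qc, k), 0)
  }

  q <- cq_to_linear(random_cq(5, 6, seed = 66, sd = 0.7), 2)
  rk <- genorm_stability(q)
  ord <- rk$gene_id[order(rk$rank, rk$m_value, rk$gene_id)]
  for (k in 2:4) {
    nf_k <- apply(q[ord[1:k], , drop = FALSE], 2, function(z) exp(mean(log(z))))
    nf_k1 <- apply(q[ord[1:(k + 1)], , drop = FALSE], 2, function(z) exp(mean(log(z))))
    expect_equal(
      genorm_pairwise_variation(q, k, ranking = rk),
      sd(log2(nf_k / nf_k1)),
      tolerance = 1e-12
    )
  }
  # sample relabeling leaves V unchanged
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(
    genorm_pairwise_variation(q[, perm], 2),
    genorm_pairwise_variation(q, 2)
  )
  expect_error(genorm_pairwise_variation(q, 1), "k must")
  expect_error(genorm_pairwise_variation(q, 5), "k must")
})

test_that("comprehensive rank is the geometric mean of method ranks with stated tie-breaks", {
  ranks <- tibble::tibble(
    gene_id = c("top", "mid"),
    rank_delta_ct = c(1, 2), rank_bestkeeper = c(1, 8),
    rank_normfinder = c(1, 4), rank_genorm = c(1, 1),
    value_delta_ct = c(0.1, 0.4)
  )
  cr <- comprehensive_rank(ranks)
  expect_equal(cr$comprehensive_geomean, c(1, 64^(1 / 4)))
  expect_equal(cr$comprehensive_geomean[2], 2.828, tolerance = 1e-3)
  expect_identical(cr$comprehensive_rank, c(1L, 2L))

  # symmetric in the method columns
  shuffled <- ranks[c(
    "gene_id", "rank_genorm", "rank_delta_ct",
    "rank_normfinder", "rank_bestkeeper", "value_delta_ct"
  )]
  names(shuffled) <- names(ranks)
  expect_equal(comprehensive_rank(shuffled)$comprehensive_geomean[1], 1)

  # equal geomeans break by delta-Ct value, then gene id
  tie <- tibble::tibble(
    gene_id = c("b", "a"),
    rank_delta_ct = c(1, 2), rank_bestkeeper = c(2, 1),
    rank_normfinder = c(1, 2), rank_genorm = c(2, 1),
    value_delta_ct = c(0.3, 0.2)
  )
  ct <- comprehensive_rank(tie)
  expect_identical(ct$comprehensive_rank[ct$gene_id == "a"], 1L)
  expect_error(comprehensive_rank(tie[-2]), "rank_delta_ct")
})

test_that("all four stability values ignore gene-wise constant Cq shifts", {
  cq <- random_cq(5, 7, seed = 67, sd = 0.6)
  cq_shift <- cq
  cq_shift[3, ] <- cq_shift[3, ] + 4.2
  for (fn in list(
    function(m) delta_ct_stability(m)$value,
    function(m) bestkeeper_stability(m)$value,
    function(m) normfinder_stability(m)$value,
    function(m) genorm_stability(cq_to_linear(m, 2))$m_value
  )) {
    expect_equal(fn(cq_shift), fn(cq), tolerance = 1e-10)
  }
})

test_that("stability_report assembles consistent values, ranks and ordering", {
  cq <- random_cq(5, 8, seed = 68, sd = 0.5)
  rep <- stability_report(cq)
  expect_identical(nrow(rep), 5L)
  expect_false(is.unsorted(rep$comprehensive_rank))
  expect_setequal(rep$comprehensive_rank, 1:5)
  expect_equal(
    sort(rep$value_delta_ct),
    sort(delta_ct_stability(cq)$value)
  )
  expect_equal(
    rep$comprehensive_geomean,
    (rep$rank_delta_ct * rep$rank_bestkeeper *
      rep$rank_normfinder * rep$rank_genorm)^(1 / 4)
  )
  expect_error(stability_report(cq[, 1:2]), ">= 3 samples")
})
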