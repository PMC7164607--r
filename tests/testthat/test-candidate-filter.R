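stoneless_groups <- function(m) {
  meta <- m$libraries
  list(
    a = meta$library_id[meta$genotype_group == "stoneless"],
    b = meta$library_id[meta$genotype_group == "normal"]
  )
}

test_that("group fold change matches direct mean/ratio arithmetic", {
  v <- rbind(
    eq = c(100, 100, 100, 100), # means 100/100 -> 1.0
    ten = c(100, 100, 110, 110), # means 100/110 -> 1.1
    both0 = c(0, 0, 0, 0),
    one0 = c(0, 0, 5, 5)
  )
  colnames(v) <- paste0("L", 1:4)
  m <- make_expr(v)
  fc <- group_fold_change(m, c("L1", "L2"), c("L3", "L4"))
  expect_equal(fc[["eq"]], 1.0)
  expect_equal(fc[["ten"]], 1.1)
  expect_true(is.na(fc[["both0"]]))
  expect_identical(fc[["one0"]], Inf)

  withr::with_seed(31, {
    r <- matrix(runif(5 * 6, 1, 100), 5, 6)
  })
  mr <- make_expr(r)
  fr <- group_fold_change(mr, c("L01", "L02", "L03"), c("L04", "L05", "L06"))
  for (i in 1:5) {
    ma <- mean(r[i, 1:3])
    mb <- mean(r[i, 4:6])
    expect_equal(unname(fr[i]), max(ma, mb) / min(ma, mb))
  }

  expect_error(group_fold_change(mr, c("L01", "L02"), c("L02", "L03")), "overlap")
  expect_error(group_fold_change(mr, character(0), "L01"), "non-empty")
})

test_that("expression window keeps exactly the genes inside the open interval", {
  means <- c(5, 36, 212, 500)
  v <- matrix(rep(means, each = 2), nrow = 4, byrow = TRUE)
  rownames(v) <- paste0("m", means)
  m <- make_expr(v)
  expect_identical(
    expression_window(m, expr_min = 11, expr_max = 450),
    c("m36", "m212")
  )
  # unbounded window is the identity
  expect_identical(expression_window(m, expr_min = 0, expr_max = Inf), rownames(v))

  withr::with_seed(32, {
    big <- matrix(runif(100 * 3, 0, 600), 100, 3)
  })
  mb <- make_expr(big)
  got <- expression_window(mb, expr_min = 11, expr_max = 450)
  want <- rownames(mb$values)[vapply(
    seq_len(100),
    function(i) mean(mb$values[i, ]) > 11 && mean(mb$values[i, ]) < 450,
    logical(1)
  )]
  expect_identical(got, want)
})

test_that("endocarp-relative dispersion score is SD over reference value", {
  v <- rbind(const = rep(10, 5), spike = c(10, 10, 10, 10, 20))
  colnames(v) <- paste0("L", 1:5)
  m <- make_expr(v)
  sc <- endocarp_relative_stability(m, reference_library = "L5")
  expect_equal(sc[["const"]], 0)
  expect_equal(sc[["spike"]], sd(c(10, 10, 10, 10, 20)) / 20)

  # scale invariance: doubling a gene leaves the score unchanged
  m2 <- make_expr(v * 2)
  expect_equal(
    endocarp_relative_stability(m2, reference_library = "L5"),
    sc
  )

  # zero in the reference library is unscorable
  v0 <- rbind(dead = c(4, 4, 4, 4, 0))
  colnames(v0) <- paste0("L", 1:5)
  expect_true(is.na(endocarp_relative_stability(make_expr(v0), reference_library = "L5")[["dead"]]))
})

test_that("cascade equals per-gene predicate enumeration and keeps nesting", {
  sim <- simulate_counts(count_sim_spec(n_genes = 500, seed = 101))
  m <- to_rpm(sim$matrix, "metadata")
  gr <- stoneless_groups(m)
  th <- filter_thresholds(
    reference_library = "L20", group_a = gr$a, group_b = gr$b
  )
  trace <- run_cascade(m, th)
  want <- oracle_cascade_sets(m, th)
  expect_setequal(trace$survivors_stage1, want$stage1)
  expect_setequal(trace$survivors_stage2, want$stage2)
  expect_setequal(trace$survivors_stage3, want$stage3)
  expect_true(all(trace$survivors_stage3 %in% trace$survivors_stage2))
  expect_true(all(trace$survivors_stage2 %in% trace$survivors_stage1))
  expect_identical(
    unname(trace$counts),
    c(500L, length(want$stage1), length(want$stage2), length(want$stage3))
  )
  # survivors ordered by ascending dispersion score
  sc <- setNames(trace$scores$stability_score, trace$scores$gene_id)
  expect_false(is.unsorted(sc[trace$survivors_stage3]))

  # gene-order invariance
  perm <- withr::with_seed(5, sample(rownames(m$values)))
  mp <- expression_matrix(m$values[perm, ], m$libraries, layer = m$layer)
  tp <- run_cascade(mp, th)
  expect_identical(tp$survivors_stage3, trace$survivors_stage3)

  # all-admitting thresholds keep every scorable gene at every stage
  th_all <- filter_thresholds(
    reference_library = "L20", group_a = gr$a, group_b = gr$b,
    fc_window = c(1, Inf), expr_min = -1, expr_max = Inf,
    stage1_stability_max = Inf, stage2_stability_max = Inf
  )
  ta <- run_cascade(m, th_all)
  scorable <- rownames(m$values)[m$values[, "L20"] > 0 &
    !is.na(trace$scores$fold_change) & is.finite(trace$scores$fold_change)]
  expect_setequal(ta$survivors_stage3, scorable)
})

test_that("constructed genes survive or fail the intended stage", {
  # 4 libraries: L1,L2 = stoneless incl. endocarp reference L2
  base <- c(100, 100, 105, 105)
  keeper <- base # fc 1.05, mean ~102, tiny dispersion score
  changer <- c(200, 200, 100, 100) # fc 2.0 -> fails stage 1
  dim_low <- rep(5, 4) # outside expression window
  v <- rbind(keeper = keeper, changer = changer, dim_low = dim_low)
  colnames(v) <- paste0("L", 1:4)
  m <- make_expr(v)
  th <- filter_thresholds(
    reference_library = "L2", group_a = c("L1", "L2"), group_b = c("L3", "L4")
  )
  tr <- run_cascade(m, th)
  expect_identical(tr$survivors_stage3, "keeper")
  expect_false("changer" %in% tr$survivors_stage1)
  expect_false("dim_low" %in% tr$survivors_stage1)
  expect_lt(tr$scores$stability_score[tr$scores$gene_id == "keeper"], 0.11)
})

test_that("loosening thresholds never shrinks survivor sets; single pass equals cascade", {
  sim <- simulate_counts(count_sim_spec(n_genes = 150, seed = 77))
  m <- to_rpm(sim$matrix, "metadata")
  gr <- stoneless_groups(m)
  for (s in 1:10) {
    withr::with_seed(1000 + s, {
      fc_hi <- runif(1, 1.05, 1.5)
      emin <- runif(1, 0, 30)
      emax <- runif(1, 200, 600)
      st1 <- runif(1, 0.1, 0.5)
      st2 <- runif(1, 0.02, st1)
    })
    th <- filter_thresholds(
      reference_library = "L20", group_a = gr$a, group_b = gr$b,
      fc_window = c(1, fc_hi), expr_min = emin, expr_max = emax,
      stage1_stability_max = st1, stage2_stability_max = st2
    )
    tr <- run_cascade(m, th)
    expect_true(all(tr$survivors_stage2 %in% tr$survivors_stage1))
    expect_true(all(tr$survivors_stage3 %in% tr$survivors_stage2))

    loose <- filter_thresholds(
      reference_library = "L20", group_a = gr$a, group_b = gr$b,
      fc_window = c(1, fc_hi * 1.3), expr_min = emin * 0.5,
      expr_max = emax * 1.5,
      stage1_stability_max = st1 * 1.5, stage2_stability_max = st2 * 1.5
    )
    tl <- run_cascade(m, loose)
    expect_true(all(tr$survivors_stage1 %in% tl$survivors_stage1))
    expect_true(all(tr$survivors_stage2 %in% tl$survivors_stage2))
    expect_true(all(tr$survivors_stage3 %in% tl$survivors_stage3))

    # stage 3 with thresholds (st1, st2) equals applying st2 directly
    direct <- filter_thresholds(
      reference_library = "L20", group_a = gr$a, group_b = gr$b,
      fc_window = c(1, fc_hi), expr_min = emin, expr_max = emax,
      stage1_stability_max = st2, stage2_stability_max = st2
    )
    expect_identical(
      run_cascade(m, direct)$survivors_stage3,
      tr$survivors_stage3
    )
  }
})

test_that("abs_log2 mode applies the window to |log2 fold change|", {
  v <- rbind(
    twofold = c(100, 100, 210, 210), # |log2| ~ 1.07 -> kept in abs_log2 mode
    flat = c(100, 100, 101, 101) # |log2| ~ 0.014 -> dropped
  )
  colnames(v) <- paste0("L", 1:4)
  m <- make_expr(v)
  th <- filter_thresholds(
    reference_library = "L2", group_a = c("L1", "L2"), group_b = c("L3", "L4"),
    fc_mode = "abs_log2", expr_min = 0, expr_max = Inf,
    stage1_stability_max = Inf, stage2_stability_max = Inf
  )
  tr <- run_cascade(m, th)
  expect_identical(tr$survivors_stage1, "twofold")
})
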