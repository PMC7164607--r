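# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are written as plain loops, deliberately not sharing
# code with the implementation they check.

make_expr <- function(values, layer = "rpm", lib_prefix = "L") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("%s%02d", lib_prefix, seq_len(ncol(values)))
  }
  expression_matrix(
    values,
    data.frame(
      library_id = colnames(values),
      total_mapped_reads = 1e6
    ),
    layer = layer
  )
}

random_cq <- function(n_genes, n_samples, seed, sd = 0.5, base = 22) {
  withr::with_seed(seed, {
    m <- matrix(
      rnorm(n_genes * n_samples, base, sd),
      nrow = n_genes,
      dimnames = list(
        sprintf("g%02d", seq_len(n_genes)),
        sprintf("s%02d", seq_len(n_samples))
      )
    )
    m
  })
}

# --- oracles -----------------------------------------------------------

oracle_delta_ct <- function(cq) {
  g <- nrow(cq)
  out <- numeric(g)
  for (i in seq_len(g)) {
    sds <- c()
    for (j in seq_len(g)) {
      if (i != j) sds <- c(sds, sd(cq[i, ] - cq[j, ]))
    }
    out[i] <- mean(sds)
  }
  names(out) <- rownames(cq)
  out
}

# geNorm M values for one round, by direct pairwise log-ratio SDs
oracle_genorm_m <- function(quantities) {
  g <- nrow(quantities)
  out <- numeric(g)
  for (i in seq_len(g)) {
    vs <- c()
    for (j in seq_len(g)) {
      if (i != j) vs <- c(vs, sd(log2(quantities[i, ] / quantities[j, ])))
    }
    out[i] <- mean(vs)
  }
  names(out) <- rownames(quantities)
  out
}

# full geNorm elimination, recomputed from scratch every round
oracle_genorm_elimination <- function(quantities) {
  active <- rownames(quantities)
  eliminated <- character(0)
  m_last <- setNames(rep(NA_real_, nrow(quantities)), rownames(quantities))
  while (length(active) > 2) {
    m <- oracle_genorm_m(quantities[active, , drop = FALSE])
    victim <- max(names(m)[m == max(m)])
    m_last[victim] <- m[victim]
    eliminated <- c(eliminated, victim)
    active <- setdiff(active, victim)
  }
  m_fin <- oracle_genorm_m(quantities[active, , drop = FALSE])
  m_last[active] <- m_fin
  list(eliminated = eliminated, survivors = active, m_last = m_last)
}

oracle_two_way_residuals <- function(y) {
  r <- y
  for (i in seq_len(nrow(y))) {
    for (j in seq_len(ncol(y))) {
      r[i, j] <- y[i, j] - mean(y[i, ]) - mean(y[, j]) + mean(y)
    }
  }
  r
}

# the replicate rule, restated independently for exhaustive checks
oracle_collapse3 <- function(x, delta = 0.5) {
  d12 <- abs(x[1] - x[2]) > delta
  d13 <- abs(x[1] - x[3]) > delta
  d23 <- abs(x[2] - x[3]) > delta
  if (d12 && d13 && d23) {
    return(list(mean = NA_real_, flag = "failed"))
  }
  if (d12 && d13) {
    return(list(mean = mean(x[2:3]), flag = "outlier_discarded"))
  }
  if (d12 && d23) {
    return(list(mean = mean(x[c(1, 3)]), flag = "outlier_discarded"))
  }
  if (d13 && d23) {
    return(list(mean = mean(x[1:2]), flag = "outlier_discarded"))
  }
  list(mean = mean(x), flag = "ok")
}

# per-gene cascade predicates, evaluated gene by gene
oracle_cascade_sets <- function(x, th) {
  genes <- rownames(x$values)
  s1 <- s2 <- s3 <- character(0)
  for (g in genes) {
    v <- x$values[g, ]
    ma <- mean(v[th$group_a])
    mb <- mean(v[th$group_b])
    fc <- if (ma == 0 && mb == 0) NA else max(ma, mb) / min(ma, mb)
    stat <- if (th$fc_mode == "ratio") fc else abs(log2(fc))
    in_fc <- !is.na(stat) && is.finite(stat) &&
      stat >= th$fc_window[1] && stat <= th$fc_window[2]
    in_expr <- mean(v) > th$expr_min && mean(v) < th$expr_max
    ref <- v[th$reference_library]
    score <- if (ref > 0) sd(v) / ref else NA
    if (in_fc && in_expr) {
      s1 <- c(s1, g)
      if (!is.na(score) && score < th$stage1_stability_max) {
        s2 <- c(s2, g)
        if (score < th$stage2_stability_max) s3 <- c(s3, g)
      }
    }
  }
  list(stage1 = s1, stage2 = s2, stage3 = s3)
}
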