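test_that("normalisation scales every sample to one million and is idempotent", {
  counts <- tibble::tibble(gene = c("g1", "g2"), a = c(1.5e6, 0.5e6),
                           b = c(9e5, 1e5))
  norm <- normalize_to_million(counts)
  expect_equal(norm$a, c(0.75e6, 0.25e6))  # total 2e6: every entry halved
  expect_equal(norm$b, counts$b)           # already at 1e6: unchanged
  expect_equal(normalize_to_million(norm), norm)

  # random integer matrix: column sums checked by independent summation
  set.seed(3)
  rand <- tibble::tibble(gene = sprintf("g%d", 1:20))
  for (s in c("s1", "s2", "s3", "s4")) {
    rand[[s]] <- stats::rpois(20, 50)
  }
  rn <- normalize_to_million(rand)
  for (s in c("s1", "s2", "s3", "s4")) {
    total <- 0
    for (i in 1:20) total <- total + rn[[s]][i]
    expect_lt(abs(total - 1e6) / 1e6, 1e-6)
  }
})

test_that("all-zero samples abort normalisation with the sample named", {
  counts <- tibble::tibble(gene = c("g1", "g2"), good = c(1, 2),
                           empty_well = c(0, 0))
  expect_error(normalize_to_million(counts), "empty_well",
               class = "xylevo_normalization_error")
})

test_that("replicate averaging is the arithmetic mean per condition", {
  tiny <- make_tiny_counts()
  avg <- average_replicates(tiny$counts, tiny$design)
  expect_equal(avg$s1_wt_glucose, c(20, 20, 20, 40))  # (10,30)/2 etc.
  expect_equal(avg$s1_wt_xylulose, c(30, 20, 30, 20))

  # single replicate: passthrough
  one <- tiny$counts[, 1:2]
  d1 <- tiny$design[1, ]
  avg1 <- average_replicates(one, d1)
  expect_equal(avg1$s1_wt_glucose, one$s1_wt_glu_r1)

  # three replicates, random values, against direct re-summation
  set.seed(7)
  r3 <- tibble::tibble(gene = c("g1", "g2"),
                       x1 = stats::runif(2), x2 = stats::runif(2),
                       x3 = stats::runif(2))
  d3 <- tibble::tibble(sample_id = c("x1", "x2", "x3"), strain = "s",
                       status = "wt", sugar = "xylulose", replicate = 1:3)
  avg3 <- average_replicates(r3, d3)
  expect_equal(avg3$s_wt_xylulose, (r3$x1 + r3$x2 + r3$x3) / 3)
})

test_that("log ratios obey symmetry, closed forms and antisymmetry", {
  avg <- make_avg_counts(list(
    s1_wt_glucose = c(100, 8, 40),
    s1_wt_xylulose = c(100, 32, 160)
  ))
  same <- log_ratio_xyl_glu(avg, pseudocount = 0)
  expect_equal(same$log2_ratio[same$gene == "g1"], 0)   # xyl = glu
  expect_equal(same$log2_ratio[same$gene == "g2"], 2)   # xyl = 4*glu
  expect_equal(same$log2_ratio[same$gene == "g3"], 2)

  # swapping the sugar labels negates every ratio
  swapped <- avg
  attr(swapped, "design")$sugar <- rev(attr(avg, "design")$sugar)
  expect_equal(log_ratio_xyl_glu(swapped, pseudocount = 0)$log2_ratio,
               -same$log2_ratio)

  # missing condition errors
  expect_error(log_ratio_xyl_glu(avg[, 1:2]), class = "xylevo_input_error")
})

test_that("simulated module effects are recovered through the ratio pipeline", {
  sim <- small_sim(seed = 13)
  avg <- average_replicates(normalize_to_million(sim$counts), sim$design)
  ratios <- log_ratio_xyl_glu(avg)
  aa_wt <- ratios |>
    dplyr::filter(.data$status == "wt",
                  .data$gene %in% sim$groups$aa_module) |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(m = mean(.data$log2_ratio))
  truth <- sim$truth$aa_effect_wt[match(aa_wt$strain, sim$truth$strain)]
  # the group-level mean across strains carries the biological signal
  expect_lt(abs(mean(aa_wt$m) - mean(truth)), 0.1)
  # per-strain estimates track the truth
  expect_gt(cor(aa_wt$m, truth), 0.5)
})

test_that("changed-gene calling respects threshold and sign consistency", {
  strains <- sprintf("s%d", 1:6)
  zero <- tidyr::expand_grid(gene = c("g1", "g2"), strain = strains)
  zero$log2_ratio <- 0
  expect_equal(nrow(identify_changed_genes(zero)), 0)

  up <- zero
  up$log2_ratio <- ifelse(up$gene == "g1", 2, 0)
  ch <- identify_changed_genes(up, threshold = 1)
  expect_equal(ch$gene, "g1")
  expect_equal(ch$direction, "up")

  # null ratios: with N(0, 0.1) noise nothing reaches a 1 log2 median;
  # verified against direct counting
  set.seed(42)
  null <- tidyr::expand_grid(gene = sprintf("g%04d", 1:1000),
                             strain = strains)
  null$log2_ratio <- stats::rnorm(nrow(null), 0, 0.1)
  called <- identify_changed_genes(null, threshold = 1)
  direct <- sum(vapply(split(null$log2_ratio, null$gene),
                       function(x) abs(median(x)) >= 1, logical(1)))
  expect_equal(nrow(called), direct)
  expect_lt(nrow(called), 1)
})

test_that("hypergeometric enrichment matches brute-force enumeration", {
  # direct tail enumeration oracle
  oracle_p <- function(overlap, set_size, universe_size, n_changed) {
    ks <- overlap:min(set_size, n_changed)
    sum(choose(set_size, ks) * choose(universe_size - set_size,
                                      n_changed - ks) /
          choose(universe_size, n_changed))
  }
  universe <- sprintf("g%02d", 1:20)
  res <- enrichment_test(universe[1:5], list(hit = universe[1:5]), universe)
  expect_equal(res$p, oracle_p(5, 5, 20, 5))

  # boundary: zero overlap has p = 1; saturated overlap also p = 1
  res0 <- enrichment_test(universe[6:10], list(miss = universe[1:5]),
                          universe)
  expect_equal(res0$p, 1)
  res_all <- enrichment_test(universe, list(grp = universe[1:7]), universe)
  expect_equal(res_all$overlap, 7)
  expect_equal(res_all$p, 1)

  # property: random set sizes over universes up to 50
  set.seed(11)
  for (i in 1:25) {
    n_univ <- sample(5:50, 1)
    univ <- sprintf("u%02d", seq_len(n_univ))
    grp <- sample(univ, sample(1:n_univ, 1))
    chg <- sample(univ, sample(1:n_univ, 1))
    res_i <- enrichment_test(chg, list(g = grp), univ)
    expect_equal(res_i$p,
                 oracle_p(res_i$overlap, length(grp), n_univ, length(chg)))
  }
})

test_that("BH q-values are monotone in p-rank and never below p at the top rank", {
  set.seed(5)
  universe <- sprintf("u%03d", 1:200)
  sets <- lapply(1:8, function(i) sample(universe, 25))
  names(sets) <- sprintf("set%d", 1:8)
  res <- enrichment_test(sample(universe, 40), sets, universe)
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_gte(res$q[ord][8], res$p[ord][8])
})

test_that("group summaries follow the gene-then-strain averaging with SE across strains", {
  ratios <- tibble::tibble(
    gene = rep(c("g1", "g2"), times = 2),
    strain = rep(c("s1", "s2"), each = 2),
    status = "wt",
    log2_ratio = c(1, 1, -1, -1)
  )
  gs <- group_summary(ratios, list(grp = c("g1", "g2")))
  expect_equal(gs$mean, 0)
  expect_equal(gs$se, 1)  # SD of {+1, -1} is sqrt(2); SE = sqrt(2)/sqrt(2)

  one <- dplyr::filter(ratios, .data$strain == "s1")
  gs1 <- group_summary(one, list(grp = c("g1", "g2")))
  expect_equal(gs1$se, 0)
  expect_true(gs1$single_strain)

  expect_warning(
    empty <- group_summary(ratios, list(absent = c("nope1", "nope2"))),
    "no genes"
  )
  expect_equal(nrow(empty), 0)
})

test_that("group summaries recover injected effects within 3 SE", {
  sim <- small_sim(seed = 17)
  avg <- average_replicates(normalize_to_million(sim$counts), sim$design)
  gs <- group_summary(log_ratio_xyl_glu(avg), sim$groups)
  aa_wt <- gs[gs$set == "aa_module" & gs$status == "wt", ]
  aa_ev <- gs[gs$set == "aa_module" & gs$status == "evolved", ]
  p <- sim$params
  expect_lt(abs(aa_wt$mean - mean(sim$truth$aa_effect_wt)), 3 * aa_wt$se)
  expect_lt(abs(aa_ev$mean - p$evolved_aa_residual),
            3 * max(aa_ev$se, 0.02))
})

test_that("per-gene group profiles divide status means by the gene's total reads", {
  # two samples only: values 30 (wt) and 10 (evolved) -> (0.75, 0.25)
  avg <- make_avg_counts(list(
    s1_wt_xylulose = c(30, 5),
    s1_evolved_xylulose = c(10, 5)
  ))
  prof <- per_gene_group_profile(avg, c("g1", "g2"))
  expect_equal(prof$wt_value[prof$gene == "g1"], 0.75)
  expect_equal(prof$evolved_value[prof$gene == "g1"], 0.25)
  # identical wt and evolved values give an equal pair
  expect_equal(prof$wt_value[prof$gene == "g2"],
               prof$evolved_value[prof$gene == "g2"])

  # random matrix against a direct two-pass recomputation
  set.seed(9)
  vals <- list(
    s1_wt_xylulose = stats::runif(6, 1, 100),
    s2_wt_xylulose = stats::runif(6, 1, 100),
    s1_evolved_xylulose = stats::runif(6, 1, 100),
    s2_evolved_xylulose = stats::runif(6, 1, 100),
    s1_wt_glucose = stats::runif(6, 1, 100),
    s2_wt_glucose = stats::runif(6, 1, 100),
    s1_evolved_glucose = stats::runif(6, 1, 100),
    s2_evolved_glucose = stats::runif(6, 1, 100)
  )
  avg_r <- make_avg_counts(vals)
  genes <- avg_r$gene[c(2, 5)]
  prof_r <- per_gene_group_profile(avg_r, genes)
  for (g in genes) {
    i <- match(g, avg_r$gene)
    total <- sum(vapply(vals, `[`, numeric(1), i))
    wt <- mean(c(vals$s1_wt_xylulose[i], vals$s2_wt_xylulose[i]))
    ev <- mean(c(vals$s1_evolved_xylulose[i], vals$s2_evolved_xylulose[i]))
    expect_equal(prof_r$wt_value[prof_r$gene == g], wt / total)
    expect_equal(prof_r$evolved_value[prof_r$gene == g], ev / total)
  }
})

test_that("gene order does not affect any pipeline result", {
  sim <- small_sim(seed = 19, n_genes = 120, n_strains = 3)
  set.seed(1)
  perm <- sample(nrow(sim$counts))
  straight <- average_replicates(normalize_to_million(sim$counts),
                                 sim$design)
  shuffled <- average_replicates(normalize_to_million(sim$counts[perm, ]),
                                 sim$design)
  r1 <- log_ratio_xyl_glu(straight)
  r2 <- log_ratio_xyl_glu(shuffled)
  r1_sorted <- dplyr::arrange(r1, .data$gene, .data$strain, .data$status)
  r2_sorted <- dplyr::arrange(r2, .data$gene, .data$strain, .data$status)
  expect_equal(r1_sorted, r2_sorted)
  expect_equal(group_summary(r1, sim$groups), group_summary(r2, sim$groups))
})
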