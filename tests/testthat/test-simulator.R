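test_that("class table and DE assignment match the reference configuration", {
  cl <- tc_class_table()
  expect_equal(cl$v1, c(5, 50, 500, 5000))
  expect_equal(cl$n, c(10000L, 8000L, 1900L, 100L))
  expect_equal(sum(cl$n), 20000L)

  # proportional apportionment at other scales is exact by construction
  cl6 <- tc_class_table(6000)
  expect_equal(sum(cl6$n), 6000L)
  expect_equal(cl6$n, c(3000L, 2400L, 570L, 30L))

  sim <- tc_simulate(tc_sim_spec("A", series = 1, replicates = 1,
                                 n_genes = 2000, seed = 1))
  expect_equal(unname(table(sim$truth$class)[c("Low", "Median", "High", "VeryHigh")]),
               c(1000L, 800L, 190L, 10L), ignore_attr = TRUE)
  expect_equal(sum(sim$truth$de), round(0.05 * 2000))
  # stratified DE: every class carries its proportional share
  de_by_class <- tapply(sim$truth$de, sim$truth$class, sum)
  expect_equal(unname(de_by_class[c("Low", "Median", "High", "VeryHigh")]),
               c(50, 40, 10, 0), ignore_attr = TRUE)

  sim0 <- tc_simulate(tc_sim_spec("A", n_genes = 500, deg_fraction = 0, seed = 2))
  expect_equal(sum(sim0$truth$de), 0L)
  expect_true(all(sim0$truth$b == 0))
})

test_that("mean profiles follow the per-scenario trend rules", {
  # scenario A, Low class: v(1) = 5 and v(6) = 5 + 0.2*5*6 = 11
  spec <- tc_sim_spec("A", n_genes = 400, times = 6, seed = 5)
  prof <- build_mean_profiles(spec)
  de_low <- prof$truth$gene_id[prof$truth$de & prof$truth$class == "Low"][1]
  expect_equal(prof$values[de_low, "s1_t1"], 5)
  expect_equal(prof$values[de_low, "s1_t6"], 11)
  # non-DE genes are flat at their class reference
  flat <- prof$truth$gene_id[!prof$truth$de & prof$truth$class == "Median"][1]
  expect_true(all(prof$values[flat, ] == 50))

  # scenario B: declining genes are shifted so the profile minimum is the floor
  specB <- tc_sim_spec("B", n_genes = 400, times = 6, seed = 5)
  profB <- build_mean_profiles(specB)
  down <- profB$truth$gene_id[profB$truth$b < 0]
  expect_gt(length(down), 0)
  mins <- apply(profB$values[down, , drop = FALSE], 1, min)
  expect_true(all(mins >= specB$floor - 1e-12))
  raw_min_low <- 5 * (1 - 0.2 * 6)          # unshifted minimum is negative
  expect_lt(raw_min_low, 0)
  low_down <- down[profB$truth$class[match(down, profB$truth$gene_id)] == "Low"]
  expect_equal(unname(mins[low_down]), rep(specB$floor, length(low_down)))

  # scenario C: spike at the second time point, then linear decline
  specC <- tc_sim_spec("C", n_genes = 400, times = 6, seed = 5)
  profC <- build_mean_profiles(specC)
  deC <- profC$truth$gene_id[profC$truth$de & profC$truth$class == "Median"][1]
  expect_equal(profC$values[deC, "s1_t2"], 4 * 50)
  expect_equal(profC$values[deC, "s1_t6"], 4 * 50 * (1 - 0.2 * 4))
  expect_true(all(diff(profC$values[deC, paste0("s1_t", 2:6)]) < 0))

  # two-series mode: the second series is flat for every gene
  spec2 <- tc_sim_spec("A", series = 2, n_genes = 300, seed = 5)
  prof2 <- build_mean_profiles(spec2)
  s2 <- prof2$values[, paste0("s2_t", 1:6)]
  expect_true(all(s2 == s2[, 1]))
})

test_that("proportions are compositional", {
  v <- matrix(c(5, 50, 500, 5, 50, 500), ncol = 2)
  p <- compute_proportions(v)
  expect_equal(colSums(p), c(1, 1), ignore_attr = TRUE)
  # doubling one gene strictly lowers every other gene's proportion
  v2 <- v; v2[1, 1] <- v2[1, 1] * 2
  p2 <- compute_proportions(v2)
  expect_true(all(p2[-1, 1] < p[-1, 1]))
  expect_gt(p2[1, 1], p[1, 1])

  # reference-configuration arithmetic at time 1
  total <- 5 * 10000 + 50 * 8000 + 500 * 1900 + 5000 * 100
  expect_equal(total, 1900000)
  prof <- build_mean_profiles(tc_sim_spec("A", n_genes = 20000, seed = 1))
  expect_equal(sum(prof$values[, "s1_t1"]), total)
  low_gene <- prof$truth$gene_id[prof$truth$class == "Low"][1]
  expect_equal(compute_proportions(prof$values)[low_gene, "s1_t1"], 5 / total)

  expect_error(compute_proportions(matrix(0, 2, 1)), "zero")
})

test_that("count draws are reproducible and match the negative binomial moments", {
  p <- matrix(1, 1, 1)
  a <- draw_counts(p, N = 100, theta = 10, replicates = 4, seed = 33)
  b <- draw_counts(p, N = 100, theta = 10, replicates = 4, seed = 33)
  expect_identical(a, b)

  n <- 1e5
  x <- draw_counts(matrix(1, 1, 1), N = 50, theta = 10, replicates = n, seed = 12)
  expect_equal(mean(x), 50, tolerance = 3 * sqrt(300 / n) / 50)
  expect_equal(var(as.numeric(x)), 50 + 50^2 / 10, tolerance = 0.05)

  # theta -> Inf recovers Poisson dispersion
  xp <- draw_counts(matrix(1, 1, 1), N = 50, theta = 1e8, replicates = n, seed = 12)
  expect_equal(var(as.numeric(xp)), 50, tolerance = 0.05)
})

test_that("simulated samples track the target depth and carry a consistent design", {
  spec <- tc_sim_spec("A", series = 2, replicates = 3, n_genes = 2000, seed = 21)
  sim <- tc_simulate(spec)
  expect_equal(dim(sim$counts), c(2000L, 6 * 2 * 3))
  expect_equal(sim$design$sample_id, colnames(sim$counts))
  # mean sample total within ~1.5% of N
  expect_lt(abs(mean(colSums(sim$counts)) / sim$N - 1), 0.015)
  # replicate groups are homogeneous by construction and times are 1..T
  expect_equal(sort(unique(sim$design$time)), 1:6)
  expect_equal(nlevels(sim$design$series), 2L)
  # identical spec and seed reproduce the dataset bit for bit
  sim2 <- tc_simulate(spec)
  expect_identical(sim$counts, sim2$counts)
})

test_that("simulation artifacts round-trip through disk including exact replay", {
  dir <- withr::local_tempdir()
  sim <- tc_simulate(tc_sim_spec("B", series = 2, replicates = 2,
                                 n_genes = 120, seed = 14))
  paths <- write_simulation(sim, dir, mtx = TRUE)
  expect_true(all(file.exists(paths)))

  counts2 <- read_counts(paths[["counts"]])
  expect_equal(counts2, sim$counts, ignore_attr = FALSE)
  counts3 <- read_counts(paths[["counts_mtx"]])
  expect_equal(unname(counts3), unname(sim$counts))

  design2 <- parse_design_table(paths[["design"]], ref_name = "series1")
  expect_equal(as.data.frame(design2), as.data.frame(sim$design))

  spec2 <- read_sim_spec(paths[["spec"]])
  sim2 <- tc_simulate(spec2)
  expect_identical(sim2$counts, sim$counts)
  expect_equal(sim2$truth, sim$truth)
})
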