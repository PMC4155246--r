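#' Expression-level class table
#'
#' Four reference expression classes used by the simulator, each defined by
#' its mean at time 1 (`v1`) and its share of genes: Low (5, 50%),
#' Median (50, 40%), High (500, 9.5%) and VeryHigh (5000, 0.5%) — 20 000
#' genes at the default scale. Other totals are apportioned proportionally by
#' largest remainder so the class sizes always sum to `n_genes` exactly.
#'
#' @param n_genes Total number of genes.
#' @return A tibble with columns `class`, `v1` and `n`.
#' @examples
#' tc_class_table()
#' tc_class_table(6000)
#' @export
tc_class_table <- function(n_genes = 20000L) {
  base <- tibble(class = c("Low", "Median", "High", "VeryHigh"),
                 v1 = c(5, 50, 500, 5000),
                 n = c(10000L, 8000L, 1900L, 100L))
  if (n_genes == 20000L) return(base)
  if (!is.numeric(n_genes) || n_genes < 4) abort("`n_genes` must be at least 4")
  base$n <- largest_remainder(base$n / 20000 * n_genes, total = n_genes)
  base
}

#' Simulation specification
#'
#' Parameters of the negative binomial time-course simulator. Counts are
#' drawn as `NB(mu = N * p_gi, size = theta)` where `p_gi` is the gene's
#' relative abundance in sample `i`, computed from per-gene mean profiles.
#' Differentially expressed genes follow a linear trend
#' `v_gt = v1 + b * v1 * t` from the second time point on: scenario `"A"`
#' raises all of them with `b = +0.2`; `"B"` splits them half up, half down
#' (`b = -0.2`), shifting profiles upward where needed so no mean falls below
#' `floor`; `"C"` spikes expression at the second time point
#' (`spike_factor` times the reference) and then declines linearly with
#' `b = -0.2`. In two-series mode the second series is flat for every gene.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param series 1 or 2 time series.
#' @param replicates Replicates per condition (positive integer).
#' @param n_genes Total genes; classes scale from [tc_class_table()].
#' @param times Number of time points `T`; times are coded `1..T`.
#' @param theta Negative binomial size parameter.
#' @param deg_fraction Fraction of genes that are differentially expressed.
#' @param b Magnitude of the linear trend coefficient.
#' @param spike_factor Scenario-C fold change at the second time point.
#' @param floor Minimum allowed mean after the scenario-B shift.
#' @param N Targeted total reads per sample; defaults to the sum of the
#'   time-1 reference means, so expected time-1 counts equal `v1`.
#' @param seed Integer seed governing gene assignment and count draws.
#' @param classes Optional custom class table (`class`, `v1`, `n`).
#'
#' @return An object of class `tc_sim_spec`.
#' @seealso [tc_simulate()]
#' @export
tc_sim_spec <- function(scenario = c("A", "B", "C"), series = 1L,
                        replicates = 3L, n_genes = 20000L, times = 6L,
                        theta = 10, deg_fraction = 0.05, b = 0.2,
                        spike_factor = 4, floor = 1, N = NULL, seed = 1L,
                        classes = NULL) {
  scenario <- match.arg(scenario)
  if (!series %in% c(1L, 2L)) abort("`series` must be 1 or 2")
  if (!is.numeric(replicates) || replicates < 1 || replicates != round(replicates))
    abort("`replicates` must be a positive integer")
  if (!is.numeric(times) || times < 2 || times != round(times))
    abort("`times` must be an integer >= 2")
  if (!is.numeric(theta) || theta <= 0) abort("`theta` must be positive")
  if (!is.numeric(deg_fraction) || deg_fraction < 0 || deg_fraction > 1)
    abort("`deg_fraction` must lie in [0, 1]")
  if (!is.numeric(b) || b <= 0) abort("`b` must be positive")
  if (!is.numeric(spike_factor) || spike_factor <= 0)
    abort("`spike_factor` must be positive")
  if (!is.numeric(floor) || floor <= 0)
    abort("`floor` must be positive (means must stay strictly positive)")
  classes <- classes %||% tc_class_table(n_genes)
  if (!all(c("class", "v1", "n") %in% names(classes)))
    abort("`classes` must have columns class, v1, n")
  if (sum(classes$n) != n_genes)
    abort("class sizes must sum to `n_genes`")
  if (any(classes$v1 <= 0)) abort("class reference means must be positive")
  structure(list(scenario = scenario, series = as.integer(series),
                 replicates = as.integer(replicates),
                 n_genes = as.integer(n_genes), times = as.integer(times),
                 theta = theta, deg_fraction = deg_fraction, b = b,
                 spike_factor = spike_factor, floor = floor, N = N,
                 seed = as.integer(seed), classes = as_tibble(classes)),
            class = "tc_sim_spec")
}

#' @export
print.tc_sim_spec <- function(x, ...) {
  cat("<tc_sim_spec> scenario", x$scenario, "|", x$series, "series |",
      x$replicates, "replicates |", x$n_genes, "genes |", x$times,
      "time points | theta =", x$theta, "| DE fraction =", x$deg_fraction,
      "| seed =", x$seed, "\n")
  invisible(x)
}

# Seeded assignment of genes to classes, DE status and trend coefficients.
# DE genes are stratified across classes by largest remainder so the total
# DE count is exactly round(deg_fraction * n_genes).
assign_genes <- function(spec) {
  cl <- spec$classes
  gene_class <- rep(cl$class, cl$n)
  v1 <- rep(cl$v1, cl$n)
  G <- spec$n_genes
  width <- nchar(as.character(G))
  gene_id <- sprintf(paste0("g%0", width, "d"), seq_len(G))

  n_de_total <- round(spec$deg_fraction * G)
  n_de_class <- largest_remainder(spec$deg_fraction * cl$n, total = n_de_total)

  de <- logical(G)
  offset <- 0L
  for (k in seq_len(nrow(cl))) {
    if (n_de_class[k] > 0L)
      de[offset + sample.int(cl$n[k], n_de_class[k])] <- TRUE
    offset <- offset + cl$n[k]
  }

  b <- numeric(G)
  idx_de <- which(de)
  if (length(idx_de)) {
    b[idx_de] <- switch(spec$scenario,
      A = spec$b,
      B = sample(rep(c(spec$b, -spec$b), length.out = length(idx_de))),
      C = -spec$b)
  }
  tibble(gene_id = gene_id, class = gene_class, v1 = v1, b = b, de = de,
         scenario = spec$scenario)
}

#' Per-gene mean expression profiles
#'
#' Builds the matrix of per-gene means `v_gi` across the time points (and
#' series) implied by the specification. Non-DE genes are flat at their class
#' reference `v1`; DE genes follow the scenario trend (see [tc_sim_spec()]).
#' The second series, when present, is flat at `v1` for all genes.
#'
#' @param spec A [tc_sim_spec()] object.
#' @param truth Optional precomputed truth table (from a previous call);
#'   when omitted, gene assignment is drawn using `spec$seed`.
#' @return A list with `values` (genes x conditions mean matrix, columns
#'   named `s<series>_t<time>`), `conditions` (tibble of series/time per
#'   column) and `truth` (gene assignment with the applied `shift`).
#' @export
build_mean_profiles <- function(spec, truth = NULL) {
  if (!inherits(spec, "tc_sim_spec")) abort("`spec` must be a tc_sim_spec object")
  if (is.null(truth)) {
    set.seed(spec$seed)
    truth <- assign_genes(spec)
  }
  Tn <- spec$times
  tt <- seq_len(Tn)
  G <- spec$n_genes

  profile_one <- function(v1, b) {
    v <- rep(v1, Tn)
    if (b != 0) {
      if (spec$scenario == "C") {
        peak <- spec$spike_factor * v1
        v[2:Tn] <- peak * (1 + b * (tt[2:Tn] - 2))
      } else {
        v[2:Tn] <- v1 + b * v1 * tt[2:Tn]
      }
    }
    shift <- max(0, spec$floor - min(v))
    list(v = v + shift, shift = shift)
  }

  V1 <- matrix(0, nrow = G, ncol = Tn)
  shift <- numeric(G)
  for (g in seq_len(G)) {
    pr <- profile_one(truth$v1[g], truth$b[g])
    V1[g, ] <- pr$v
    shift[g] <- pr$shift
  }
  if (any(V1 <= 0))
    abort("simulation parameters yield non-positive means after the shift")
  truth$shift <- shift

  if (spec$series == 2L) {
    V <- cbind(V1, matrix(truth$v1, nrow = G, ncol = Tn))
    conds <- tibble(series = rep(1:2, each = Tn), time = rep(tt, 2))
  } else {
    V <- V1
    conds <- tibble(series = rep(1L, Tn), time = tt)
  }
  colnames(V) <- paste0("s", conds$series, "_t", conds$time)
  rownames(V) <- truth$gene_id
  list(values = V, conditions = conds, truth = truth)
}

#' Relative gene abundances
#'
#' Converts per-gene means into compositional proportions per sample,
#' `p_gi = v_gi / sum_g v_gi`, so each column sums to 1 and raising one
#' gene's expression lowers every other gene's proportion — the composition
#' of the RNA population is modelled, not only absolute levels.
#'
#' @param v Non-negative genes x samples matrix of means.
#' @return A matrix of the same shape with unit column sums.
#' @export
compute_proportions <- function(v) {
  m <- as.matrix(v)
  if (anyNA(m) || any(m < 0)) abort("mean profiles must be non-negative")
  cs <- colSums(m)
  if (any(cs <= 0)) abort("a sample column has zero total mean expression")
  sweep(m, 2, cs, "/")
}

#' Draw negative binomial counts
#'
#' Samples counts for every gene and replicate: each count is
#' `NB(mu = N * p, size = theta)`, independent across genes and replicates.
#' Column order is condition-major (all replicates of the first condition
#' first).
#'
#' @param p Genes x conditions proportion matrix (see
#'   [compute_proportions()]).
#' @param N Targeted total reads per sample.
#' @param theta Negative binomial size parameter.
#' @param replicates Replicates per condition.
#' @param seed Optional seed; set it for a reproducible standalone draw (the
#'   full simulator seeds once in [tc_simulate()]).
#' @return An integer-valued genes x samples matrix.
#' @export
draw_counts <- function(p, N, theta, replicates = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- as.matrix(p)
  G <- nrow(m)
  cols <- vector("list", ncol(m) * replicates)
  nm <- character(length(cols))
  k <- 0L
  for (j in seq_len(ncol(m))) {
    mu <- N * m[, j]
    for (r in seq_len(replicates)) {
      k <- k + 1L
      cols[[k]] <- stats::rnbinom(G, mu = mu, size = theta)
      nm[k] <- paste0(colnames(m)[j] %||% paste0("c", j), "_r", r)
    }
  }
  counts <- do.call(cbind, cols)
  dimnames(counts) <- list(rownames(m), nm)
  counts
}

#' Simulate an RNA-seq time-course dataset with known truth
#'
#' Full generator: assigns genes to expression classes and differential
#' expression status, builds the scenario mean profiles, converts them to
#' compositional proportions and draws negative binomial counts for every
#' replicate. The result carries the matching experimental design and the
#' per-gene truth table for confusion-matrix scoring. All genes have a
#' constant notional length (1 kb), so no length correction applies.
#'
#' @param spec A [tc_sim_spec()] object.
#' @return An object of class `tc_sim`: a list with `counts` (genes x
#'   samples), `design` ([tc_design()]), `truth` (gene_id, class, v1, b, de,
#'   scenario, shift), `mean_profiles`, `N` and `spec`.
#' @examples
#' sim <- tc_simulate(tc_sim_spec("A", series = 2, replicates = 2,
#'                                n_genes = 400, seed = 7))
#' dim(sim$counts); sum(sim$truth$de)
#' @export
tc_simulate <- function(spec) {
  if (!inherits(spec, "tc_sim_spec")) abort("`spec` must be a tc_sim_spec object")
  set.seed(spec$seed)
  truth <- assign_genes(spec)
  prof <- build_mean_profiles(spec, truth = truth)
  P <- compute_proportions(prof$values)
  N <- spec$N %||% sum(prof$values[, 1L])
  counts <- draw_counts(P, N, spec$theta, replicates = spec$replicates)

  conds <- prof$conditions
  design_df <- data.frame(
    sample_id = colnames(counts),
    time = rep(conds$time, each = spec$replicates),
    replicate = rep(seq_len(nrow(conds)), each = spec$replicates),
    series = paste0("series", rep(conds$series, each = spec$replicates)),
    stringsAsFactors = FALSE)
  design <- tc_design(design_df, ref = "series1")

  structure(list(counts = counts, design = design, truth = prof$truth,
                 mean_profiles = prof$values, N = N, spec = spec),
            class = "tc_sim")
}

#' @export
print.tc_sim <- function(x, ...) {
  cat("<tc_sim>", nrow(x$counts), "genes x", ncol(x$counts), "samples |",
      sum(x$truth$de), "DE genes | scenario", x$spec$scenario, "| seed",
      x$spec$seed, "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the counts (TSV, and optionally matrix-market triplet with id
#' sidecars), the design table, the truth table, and the specification as
#' JSON (including the seed) so the dataset can be regenerated exactly with
#' [read_sim_spec()] + [tc_simulate()].
#'
#' @param sim A [tc_simulate()] result.
#' @param dir Output directory (created if needed).
#' @param mtx Also write a sparse matrix-market copy of the counts.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_simulation <- function(sim, dir, mtx = FALSE) {
  if (!inherits(sim, "tc_sim")) abort("`sim` must be a tc_sim object")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"),
             spec = file.path(dir, "spec.json"))
  write_counts(sim$counts, paths[["counts"]])
  write_design_table(sim$design, paths[["design"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spec <- sim$spec
  jsonlite::write_json(
    list(scenario = spec$scenario, series = spec$series,
         replicates = spec$replicates, n_genes = spec$n_genes,
         times = spec$times, theta = spec$theta,
         deg_fraction = spec$deg_fraction, b = spec$b,
         spike_factor = spec$spike_factor, floor = spec$floor,
         N = spec$N, seed = spec$seed),
    paths[["spec"]], auto_unbox = TRUE, digits = NA, null = "null")
  if (mtx) {
    paths <- c(paths, counts_mtx = file.path(dir, "counts.mtx"))
    write_counts(sim$counts, paths[["counts_mtx"]], format = "mtx")
  }
  invisible(paths)
}

#' Read a simulation specification back from JSON
#'
#' @param path Path to a `spec.json` written by [write_simulation()].
#' @return A [tc_sim_spec()] object that regenerates the dataset exactly.
#' @export
read_sim_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tc_sim_spec(scenario = x$scenario, series = x$series,
              replicates = x$replicates, n_genes = x$n_genes,
              times = x$times, theta = x$theta,
              deg_fraction = x$deg_fraction, b = x$b,
              spike_factor = x$spike_factor, floor = x$floor,
              N = x$N, seed = x$seed)
}
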