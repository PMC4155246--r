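#' Score a gene selection against simulation truth
#'
#' Exact confusion summary of a selected gene set: number selected (`Sel`),
#' false positives and false negatives, the empirical false discovery rate
#' `FDR = FP / Sel` and the false non-discovery rate `FNR = FN / (G - Sel)`.
#' By convention `FDR = 0` when nothing is selected and `FNR = 0` when
#' everything is.
#'
#' @param selected Character vector of selected gene ids, or a
#'   [tc_select()] tibble (its `selected` rows are used).
#' @param truth A truth table with columns `gene_id` and logical `de`
#'   (e.g. `tc_simulate(...)$truth`).
#' @return A one-row tibble of class `tc_confusion`: `selected`,
#'   `false_positives`, `false_negatives`, `fdr`, `fnr`, `n_genes`, `n_de`.
#' @examples
#' truth <- tibble::tibble(gene_id = paste0("g", 1:10),
#'                         de = c(rep(TRUE, 3), rep(FALSE, 7)))
#' tc_score(c("g1", "g4"), truth)  # fdr 0.5, fnr 2/8
#' @export
tc_score <- function(selected, truth) {
  if (is.data.frame(selected)) {
    if (!all(c("gene_id", "selected") %in% names(selected)))
      abort("a data-frame `selected` needs columns gene_id and selected")
    selected <- selected$gene_id[selected$selected]
  }
  selected <- unique(as.character(selected))
  if (!is.data.frame(truth) || !all(c("gene_id", "de") %in% names(truth)))
    abort("`truth` must be a data frame with columns gene_id and de")
  unknown <- setdiff(selected, truth$gene_id)
  if (length(unknown))
    abort(paste0("selected gene id(s) absent from the truth table: ",
                 paste(unknown[1:min(3, length(unknown))], collapse = ", ")))

  g <- nrow(truth)
  de <- truth$gene_id[truth$de]
  sel <- length(selected)
  fp <- length(setdiff(selected, de))
  fn <- length(setdiff(de, selected))
  out <- tibble(selected = sel, false_positives = fp, false_negatives = fn,
                fdr = if (sel == 0) 0 else fp / sel,
                fnr = if (sel == g) 0 else fn / (g - sel),
                n_genes = g, n_de = length(de))
  class(out) <- c("tc_confusion", class(out))
  out
}

#' Sweep the R-squared cutoff
#'
#' Re-applies the goodness-of-fit filter over a grid of cutoffs and scores
#' each resulting selection against the truth table. The step-1 and step-2
#' fits are computed once (they live in `models`); the cutoff is a pure
#' filter, so the number selected is non-increasing along the grid and the
#' `rsq = 0` row reproduces the step-1-only selection.
#'
#' @param models A [tc_stepwise()] result for the step-1-selected genes.
#' @param truth Truth table (see [tc_score()]).
#' @param rsq_grid Cutoff grid.
#' @return A tibble of class `tc_sweep`: one row per cutoff with the
#'   confusion summary columns.
#' @seealso [autoplot.tc_sweep()]
#' @export
tc_rsq_sweep <- function(models, truth, rsq_grid = seq(0, 0.9, by = 0.1)) {
  if (!inherits(models, "tc_models")) abort("`models` must be a tc_models object")
  rows <- lapply(rsq_grid, function(r) {
    sc <- tc_score(tc_select(models, rsq = r), truth)
    dplyr::bind_cols(tibble(rsq = r), sc)
  })
  out <- bind_rows(rows)
  class(out) <- c("tc_sweep", setdiff(class(out), "tc_confusion"))
  out
}

#' Benchmark the pipeline over a simulation grid
#'
#' Runs the full simulate / normalize / screen / stepwise / select / score
#' pipeline over every combination of scenario, number of series and
#' replication level, with `n_seeds` independent datasets per cell. Each
#' cell-and-repeat gets a deterministic seed derived from `base_seed` and the
#' cell coordinates, recorded in the output, so partial re-runs reproduce the
#' same datasets. Failures of an individual cell are recorded in the `error`
#' column and the grid continues.
#'
#' @param scenarios,series,replicates Vectors defining the grid.
#' @param n_seeds Independent simulated datasets per cell.
#' @param base_seed Base seed from which cell seeds are derived.
#' @param n_genes,times,theta,deg_fraction Simulator settings
#'   (see [tc_sim_spec()]); the 6000-gene default keeps runs desk-scale
#'   while behaving like the full-size configuration.
#' @param degree,alpha,rsq,step_alpha Pipeline settings.
#' @param family Optional [tc_family()] override; defaults to the negative
#'   binomial with the simulator's `theta`.
#' @param normalize Apply TMM normalization before fitting (default TRUE).
#' @param max_cells Guard: warn when the grid exceeds this many runs.
#' @param verbose Progress messages.
#'
#' @return A tibble of class `tc_benchmark`: one row per (scenario, series,
#'   replicates, seed) with the confusion summary and any error message.
#' @seealso [tc_benchmark_summary()]
#' @export
tc_benchmark <- function(scenarios = "A", series = 2L, replicates = c(2L, 3L, 5L),
                         n_seeds = 3L, base_seed = 1L, n_genes = 6000L,
                         times = 6L, theta = 10, deg_fraction = 0.05,
                         degree = 2L, alpha = 0.05, rsq = 0.7,
                         step_alpha = 0.05, family = NULL, normalize = TRUE,
                         max_cells = 60L, verbose = FALSE) {
  grid <- expand.grid(rep_idx = seq_len(n_seeds), replicates = replicates,
                      series = series, scenario = scenarios,
                      stringsAsFactors = FALSE)
  if (nrow(grid) > max_cells)
    warn(paste0("benchmark grid has ", nrow(grid), " runs; this may take a while"))

  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    cell_seed <- derive_seed(base_seed, cell$scenario, cell$series,
                             cell$replicates, cell$rep_idx)
    head_tbl <- tibble(scenario = cell$scenario, series = cell$series,
                       replicates = cell$replicates, rep_idx = cell$rep_idx,
                       seed = cell_seed)
    rows[[i]] <- tryCatch({
      sim <- tc_simulate(tc_sim_spec(
        scenario = cell$scenario, series = cell$series,
        replicates = cell$replicates, n_genes = n_genes, times = times,
        theta = theta, deg_fraction = deg_fraction, seed = cell_seed))
      counts <- sim$counts
      if (normalize) counts <- apply_normalization(counts, tmm_factors(counts))
      fam <- family %||% tc_family("negative_binomial", theta = theta)
      scr <- tc_screen(counts, sim$design, degree = degree, family = fam,
                       alpha = alpha)
      mods <- tc_stepwise(counts, scr, step_alpha = step_alpha)
      sel <- tc_select(mods, rsq = rsq)
      dplyr::bind_cols(head_tbl, tc_score(sel, sim$truth),
                       tibble(error = NA_character_))
    }, error = function(e) {
      dplyr::bind_cols(head_tbl,
                       tibble(selected = NA_integer_,
                              false_positives = NA_integer_,
                              false_negatives = NA_integer_,
                              fdr = NA_real_, fnr = NA_real_,
                              n_genes = NA_integer_, n_de = NA_integer_,
                              error = conditionMessage(e)))
    })
    if (verbose)
      inform(sprintf("benchmark %d/%d: scenario %s, %d series, %d reps, seed %d",
                     i, nrow(grid), cell$scenario, cell$series,
                     cell$replicates, cell_seed))
  }
  out <- bind_rows(rows)
  class(out) <- c("tc_benchmark", setdiff(class(out), "tc_confusion"))
  attr(out, "base_seed") <- base_seed
  out
}

#' Aggregate a benchmark over its seeds
#'
#' Mean (and Monte-Carlo standard error) of the FDR and FNR per grid cell,
#' averaging over the repeated seeds.
#'
#' @param bench A [tc_benchmark()] result.
#' @return A tibble with one row per (scenario, series, replicates) cell.
#' @export
tc_benchmark_summary <- function(bench) {
  if (!is.data.frame(bench)) abort("`bench` must be a tc_benchmark tibble")
  mc_se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  bench |>
    dplyr::filter(is.na(.data$error)) |>
    group_by(.data$scenario, .data$series, .data$replicates) |>
    summarise(n_runs = dplyr::n(),
              mean_selected = mean(.data$selected),
              mean_fdr = mean(.data$fdr), se_fdr = mc_se(.data$fdr),
              mean_fnr = mean(.data$fnr), se_fnr = mc_se(.data$fnr),
              .groups = "drop")
}
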