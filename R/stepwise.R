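#' Stepwise coefficient selection for a single gene
#'
#' Finds the best polynomial sub-model for one gene. Backward elimination
#' (the default) starts from the full step-1 design and repeatedly refits
#' after removing the non-intercept term whose single-term likelihood-ratio
#' p-value is largest, as long as that p-value exceeds `step_alpha`; ties are
#' broken by dropping the highest-order (right-most) column first. Forward
#' selection is the mirror image, adding the most significant candidate while
#' it clears `step_alpha`. The intercept is never a candidate. Aliased
#' (non-estimable) terms and terms whose reduced fit fails to converge are
#' dropped with a note. By default the retained-coefficient hierarchy is not
#' enforced — a `time^2` term may survive without `time` — matching the
#' "retain exactly the significant coefficients" behaviour; `hierarchy =
#' TRUE` restricts removal to terms with no retained higher-order companion.
#'
#' @param y Response vector for one gene.
#' @param X A [build_design_matrix()] object (the step-1 design).
#' @param family A [tc_family()] object.
#' @param step_alpha Per-term significance level (default 0.05).
#' @param direction `"backward"` (default) or `"forward"`.
#' @param test `"lrt"` for single-term deviance-difference chi-square tests
#'   (the default, consistent with the screening test) or `"wald"`.
#' @param hierarchy Enforce strict polynomial hierarchy during elimination.
#' @param gene_id Optional label carried into the result.
#'
#' @return A list of class `tc_gene_model`: `gene_id`, `retained` (term
#'   names, intercept first), `coefficients`, `coef_p` (per retained
#'   non-intercept term), `r_squared`, `final_deviance`, `null_deviance`,
#'   `converged` and `notes`.
#' @export
stepwise_select <- function(y, X, family = tc_family(), step_alpha = 0.05,
                            direction = c("backward", "forward"),
                            test = c("lrt", "wald"),
                            hierarchy = FALSE, gene_id = NA_character_) {
  direction <- match.arg(direction)
  test <- match.arg(test)
  if (!is.numeric(step_alpha) || step_alpha < 0 || step_alpha > 1)
    abort("`step_alpha` must lie in [0, 1]")
  x <- design_values(X)
  terms_all <- colnames(x)
  cand <- terms_all[-1L]
  notes <- character()

  fit_on <- function(keep) {
    fit_glm(y, x[, c(terms_all[1L], keep), drop = FALSE], family = family)
  }

  # single-term p-values for removing each element of `keep` from fit_cur
  drop_p <- function(fit_cur, keep, subset = keep) {
    if (test == "wald") {
      w <- wald_p_values(fit_cur)
      return(w[subset])
    }
    vapply(subset, function(j) {
      f2 <- fit_on(setdiff(keep, j))
      if (!isTRUE(f2$converged)) return(NA_real_)
      delta <- max(f2$deviance - fit_cur$deviance, 0)
      stats::pchisq(delta / fit_dispersion(fit_cur), df = 1, lower.tail = FALSE)
    }, numeric(1))
  }

  null_fit <- fit_on(character())

  if (direction == "backward") {
    keep <- cand
    fit_cur <- fit_on(keep)
    repeat {
      al <- intersect(fit_cur$aliased, keep)
      if (length(al)) {
        notes <- c(notes, paste0("dropped aliased term(s): ", paste(al, collapse = ", ")))
        keep <- setdiff(keep, al)
        fit_cur <- fit_on(keep)
        next
      }
      if (!isTRUE(fit_cur$converged)) {
        if (!length(keep)) { fit_cur <- null_fit; break }
        j <- keep[length(keep)]
        notes <- c(notes, paste0("non-convergence; treated '", j, "' as non-estimable"))
        keep <- setdiff(keep, j)
        fit_cur <- fit_on(keep)
        next
      }
      if (!length(keep)) break
      droppable <- if (hierarchy) hier_droppable(keep, terms_all) else keep
      if (!length(droppable)) break
      p <- drop_p(fit_cur, keep, droppable)
      if (anyNA(p)) {
        j <- droppable[max(which(is.na(p)))]
        notes <- c(notes, paste0("non-convergence; treated '", j, "' as non-estimable"))
        keep <- setdiff(keep, j)
        fit_cur <- fit_on(keep)
        next
      }
      worst <- max(p)
      if (worst > step_alpha) {
        ties <- droppable[p == worst]
        j <- ties[length(ties)]            # highest-order column dropped first
        keep <- setdiff(keep, j)
        fit_cur <- fit_on(keep)
      } else break
    }
  } else {
    keep <- character()
    fit_cur <- null_fit
    repeat {
      rem <- setdiff(cand, keep)
      if (hierarchy) rem <- hier_addable(rem, keep, terms_all)
      if (!length(rem)) break
      p <- vapply(rem, function(j) {
        f2 <- fit_on(cand[cand %in% c(keep, j)])
        if (!isTRUE(f2$converged)) return(NA_real_)
        delta <- max(fit_cur$deviance - f2$deviance, 0)
        stats::pchisq(delta / fit_dispersion(f2), df = 1, lower.tail = FALSE)
      }, numeric(1))
      if (all(is.na(p))) break
      best <- min(p, na.rm = TRUE)
      if (best <= step_alpha) {
        j <- rem[which(!is.na(p) & p == best)][1L]   # lowest-order candidate first
        keep <- cand[cand %in% c(keep, j)]
        fit_cur <- fit_on(keep)
        if (!isTRUE(fit_cur$converged)) {
          notes <- c(notes, paste0("non-convergence when adding '", j, "'; reverted"))
          keep <- setdiff(keep, j)
          fit_cur <- fit_on(keep)
          break
        }
      } else break
    }
  }

  coef_p <- if (length(keep)) drop_p(fit_cur, keep) else stats::setNames(numeric(0), character(0))
  beta <- fit_cur$coefficients[!is.na(fit_cur$coefficients)]
  structure(list(
    gene_id = gene_id,
    retained = c(terms_all[1L], keep),
    coefficients = beta,
    coef_p = coef_p,
    r_squared = goodness_of_fit(fit_cur),
    final_deviance = fit_cur$deviance,
    null_deviance = fit_cur$null_deviance,
    converged = fit_cur$converged,
    notes = notes), class = "tc_gene_model")
}

# terms whose removal keeps the model hierarchical: no retained higher-order
# term of the same series block may depend on them
hier_droppable <- function(keep, terms_all) {
  info <- lapply(keep, parse_term)
  ok <- vapply(seq_along(keep), function(i) {
    !any(vapply(seq_along(keep), function(j) {
      i != j && identical(info[[j]]$series, info[[i]]$series) &&
        info[[j]]$power > info[[i]]$power
    }, logical(1)))
  }, logical(1))
  keep[ok]
}

hier_addable <- function(rem, keep, terms_all) {
  rem[vapply(rem, function(j) {
    pj <- parse_term(j)
    if (pj$power == 0) return(TRUE)
    lower <- Filter(function(t) {
      pt <- parse_term(t)
      identical(pt$series, pj$series) && pt$power < pj$power
    }, setdiff(terms_all[-1L], keep))
    length(lower) == 0L
  }, logical(1))]
}

parse_term <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
  if (length(parts) == 2L) {
    list(series = parts[2L], power = term_power(parts[1L]))
  } else if (grepl("^time[0-9]*$", parts[1L])) {
    list(series = NA_character_, power = term_power(parts[1L]))
  } else {
    list(series = parts[1L], power = 0)
  }
}

term_power <- function(s) {
  if (s == "time") return(1)
  as.numeric(sub("^time", "", s))
}

#' Deviance-explained goodness of fit
#'
#' The percentage of deviance explained by a fitted model,
#' `(D0 - D) / D0`, clipped to `[0, 1]`; the GLM analogue of the classical
#' coefficient of determination (and exactly equal to `1 - RSS/TSS` for the
#' gaussian family). A perfectly constant gene (`D0 = 0`) is assigned 0.
#'
#' @param fit A [fit_glm()] object.
#' @return A scalar in `[0, 1]`.
#' @export
goodness_of_fit <- function(fit) {
  d0 <- fit$null_deviance
  d <- fit$deviance
  if (!is.finite(d0) || d0 <= 0 || !is.finite(d)) return(0)
  min(max((d0 - d) / d0, 0), 1)
}

#' Step 2: per-gene stepwise model selection
#'
#' Runs [stepwise_select()] on every screened gene (by default those selected
#' in step 1), retaining only significant coefficients and computing the
#' deviance-explained R-squared of each optimised model.
#'
#' @inheritParams tc_screen
#' @param screen A [tc_screen()] result (carries the design matrix and
#'   family).
#' @param genes Gene ids to model; defaults to the step-1 selection.
#' @param step_alpha,direction,test,hierarchy Passed to [stepwise_select()].
#'
#' @return A tibble of class `tc_models`, one row per gene: `gene_id`,
#'   `n_terms`, `retained` / `coefficients` / `coef_p` list-columns,
#'   `r_squared`, `final_deviance`, `null_deviance`, `converged`, `notes`.
#' @seealso [tc_select()] for the final R-squared filter,
#'   [fitted_profiles()] for the fitted mean profiles.
#' @export
tc_stepwise <- function(counts, screen, genes = NULL, step_alpha = 0.05,
                        direction = c("backward", "forward"),
                        test = c("lrt", "wald"), hierarchy = FALSE) {
  direction <- match.arg(direction)
  test <- match.arg(test)
  if (!inherits(screen, "tc_screen")) abort("`screen` must be a tc_screen object")
  m <- as_counts_matrix(counts)
  design <- attr(screen, "design")
  X <- attr(screen, "design_matrix")
  family <- attr(screen, "family")
  if (!is.null(colnames(m))) m <- m[, design$sample_id, drop = FALSE]

  genes <- genes %||% screen$gene_id[screen$selected]
  if (is.null(rownames(m))) rownames(m) <- paste0("gene", seq_len(nrow(m)))
  unknown <- setdiff(genes, rownames(m))
  if (length(unknown))
    abort(paste0("gene id(s) not in the count matrix: ",
                 paste(unknown[1:min(3, length(unknown))], collapse = ", ")))

  models <- lapply(genes, function(g) {
    stepwise_select(m[g, ], X, family = family, step_alpha = step_alpha,
                    direction = direction, test = test, hierarchy = hierarchy,
                    gene_id = g)
  })

  out <- tibble(
    gene_id = as.character(genes),
    n_terms = vapply(models, function(z) length(z$retained) - 1L, integer(1)),
    retained = lapply(models, `[[`, "retained"),
    coefficients = lapply(models, `[[`, "coefficients"),
    coef_p = lapply(models, `[[`, "coef_p"),
    r_squared = vapply(models, `[[`, numeric(1), "r_squared"),
    final_deviance = vapply(models, `[[`, numeric(1), "final_deviance"),
    null_deviance = vapply(models, `[[`, numeric(1), "null_deviance"),
    converged = vapply(models, `[[`, logical(1), "converged"),
    notes = vapply(models, function(z) paste(z$notes, collapse = "; "), character(1)))
  class(out) <- c("tc_models", class(out))
  attr(out, "design_matrix") <- X
  attr(out, "design") <- design
  attr(out, "family") <- family
  attr(out, "step_alpha") <- step_alpha
  attr(out, "direction") <- direction
  attr(out, "test") <- test
  out
}

#' @rdname tc_stepwise
#' @param x,object A `tc_models` object.
#' @param ... Unused.
#' @method tidy tc_models
#' @export
tidy.tc_models <- function(x, ...) {
  rows <- lapply(seq_len(nrow(x)), function(i) {
    b <- x$coefficients[[i]]
    p <- x$coef_p[[i]]
    tibble(gene_id = x$gene_id[i], term = names(b), estimate = unname(b),
           p_value = unname(p[match(names(b), names(p))]),
           r_squared = x$r_squared[i])
  })
  bind_rows(rows)
}

#' @rdname tc_stepwise
#' @method glance tc_models
#' @export
glance.tc_models <- function(x, ...) {
  tibble(n_genes = nrow(x), mean_terms = mean(x$n_terms),
         mean_r_squared = mean(x$r_squared),
         n_converged = sum(x$converged),
         step_alpha = attr(x, "step_alpha"),
         direction = attr(x, "direction"))
}

#' Fitted mean profiles of the optimised gene models
#'
#' Evaluates each gene's final model over the design samples on the response
#' scale, producing a genes x samples matrix of fitted means suitable for
#' export, plotting or clustering.
#'
#' @param models A [tc_stepwise()] result.
#' @return A numeric matrix with one row per modelled gene.
#' @export
fitted_profiles <- function(models) {
  if (!inherits(models, "tc_models")) abort("`models` must be a tc_models object")
  X <- attr(models, "design_matrix")
  fam <- attr(models, "family")
  x <- design_values(X)
  mu <- t(vapply(seq_len(nrow(models)), function(i) {
    b <- models$coefficients[[i]]
    eta <- drop(x[, names(b), drop = FALSE] %*% b)
    fam$linkinv(eta)
  }, numeric(nrow(x))))
  dimnames(mu) <- list(models$gene_id, rownames(x))
  mu
}

#' Final gene selection with the goodness-of-fit filter
#'
#' Combines the step-1 significance screen (the genes present in `models`)
#' with the deviance-explained R-squared cutoff: a gene makes the final list
#' when its optimised model explains at least `rsq` of its null deviance.
#' With `rsq = 0` the filter is disabled and the final selection equals the
#' step-1 selection. Per-series involvement is reported by whether any dummy
#' or interaction term of that series was retained, and `trend_reference`
#' flags genes whose model retains a time term shared with the reference
#' series.
#'
#' @param models A [tc_stepwise()] result.
#' @param rsq R-squared cutoff in `[0, 1]`; 0.7 is a good default for
#'   simulated-scale data, 0.5 is reasonable for well-replicated multi-series
#'   designs.
#' @return A tibble of class `tc_selection` with `gene_id`, `r_squared`,
#'   `selected` and per-series flags.
#' @export
tc_select <- function(models, rsq = 0.7) {
  if (!inherits(models, "tc_models")) abort("`models` must be a tc_models object")
  if (!is.numeric(rsq) || length(rsq) != 1L || is.na(rsq) || rsq < 0 || rsq > 1)
    abort("`rsq` must be a single value in [0, 1]")
  X <- attr(models, "design_matrix")
  out <- tibble(gene_id = models$gene_id,
                r_squared = models$r_squared,
                selected = models$r_squared >= rsq)
  out$trend_reference <- map_lgl(models$retained, function(terms) {
    any(grepl("^time[0-9]*$", terms))
  })
  for (s in X$series_levels[-1L]) {
    out[[paste0("series_", s)]] <- map_lgl(models$retained, function(terms) {
      any(terms == s | endsWith(terms, paste0(":", s)))
    })
  }
  class(out) <- c("tc_selection", class(out))
  attr(out, "rsq") <- rsq
  out
}
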