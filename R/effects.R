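#' Per-day block and genotype effects on holistic phenotypes
#'
#' For each imaging day t and response h (plant aerial density, bi-angular
#' convex-hull area ratio or plant aspect ratio), the phenotype of plant j
#' in greenhouse block i is modeled as
#' y = mu + alpha_i + gamma_g + epsilon, an ordinary least-squares fit
#' under reference (treatment) coding: the first block and the benchmark
#' genotype have effect exactly zero, so every alpha is a difference from
#' the reference block and every gamma a difference from the benchmark
#' genotype.  Days are fitted independently; intervals are t-based with
#' the residual degrees of freedom and no multiplicity correction.
#'
#' @name effects_model
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Fit the block + genotype model for one day
#'
#' @param table long-format phenotype table with columns `plant_id`,
#'   `block`, `genotype`, `day`, `response`, `value`.
#' @param day imaging day to fit.
#' @param response response name to fit (e.g. `"pad"`).
#' @param benchmark_block,benchmark_genotype reference levels; defaults
#'   are the first levels in sort order.
#' @return a `day_fit` object wrapping the OLS fit.
#' @export
fit_day_model <- function(table, day, response,
                          benchmark_block = NULL, benchmark_genotype = NULL) {
  dd <- table[table$day == day & table$response == response, , drop = FALSE]
  if (nrow(dd) == 0) abort("no rows for that day/response")
  dd$block <- factor(dd$block)
  dd$genotype <- factor(dd$genotype)
  if (nlevels(dd$block) < 2 || nlevels(dd$genotype) < 2)
    abort("need at least 2 blocks and 2 genotypes represented on the day")
  if (!is.null(benchmark_block)) dd$block <- stats::relevel(dd$block, as.character(benchmark_block))
  if (!is.null(benchmark_genotype)) dd$genotype <- stats::relevel(dd$genotype, as.character(benchmark_genotype))
  fit <- lm(value ~ block + genotype, data = dd,
            contrasts = list(block = "contr.treatment", genotype = "contr.treatment"))
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("aliased effects (confounded levels): ", paste(bad, collapse = ", ")),
          class = "aliased_effects")
  }
  structure(
    list(model = fit, day = day, response = response,
         benchmark_block = levels(dd$block)[1],
         benchmark_genotype = levels(dd$genotype)[1],
         blocks = levels(dd$block), genotypes = levels(dd$genotype)),
    class = "day_fit"
  )
}

#' @export
print.day_fit <- function(x, ...) {
  cat("<day_fit> day ", x$day, ", response '", x$response, "': ",
      length(x$blocks), " blocks, ", length(x$genotypes),
      " genotypes (benchmarks: block ", x$benchmark_block,
      ", genotype ", x$benchmark_genotype, ")\n", sep = "")
  invisible(x)
}

#' @rdname fit_day_model
#' @param x a `day_fit`.
#' @param conf_level confidence level for the intervals.
#' @param ... unused.
#' @export
tidy.day_fit <- function(x, conf_level = 0.95, ...) {
  fit <- x$model
  cf <- coef(fit)
  se <- sqrt(diag(suppressWarnings(vcov(fit))))  # zero-residual fits are legal
  tcrit <- qt(1 - (1 - conf_level) / 2, fit$df.residual)
  term <- names(cf)
  type <- dplyr::case_when(
    term == "(Intercept)" ~ "intercept",
    grepl("^block", term) ~ "block",
    TRUE ~ "genotype"
  )
  level <- sub("^(block|genotype)", "", term)
  level[type == "intercept"] <- NA_character_
  base <- tibble::tibble(
    day = x$day, response = x$response, term_type = type, level = level,
    estimate = unname(cf), std_error = unname(se),
    conf_low = unname(cf - tcrit * se), conf_high = unname(cf + tcrit * se)
  )
  refs <- tibble::tibble(
    day = x$day, response = x$response,
    term_type = c("block", "genotype"),
    level = c(x$benchmark_block, x$benchmark_genotype),
    estimate = 0, std_error = 0, conf_low = 0, conf_high = 0
  )
  dplyr::arrange(dplyr::bind_rows(base, refs),
                 factor(.data$term_type, c("intercept", "block", "genotype")),
                 .data$level)
}

#' @rdname fit_day_model
#' @export
glance.day_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))
  tibble::tibble(
    day = x$day, response = x$response,
    sigma = s$sigma, r_squared = s$r.squared,
    df_residual = x$model$df.residual,
    n = length(x$model$residuals)
  )
}

#' Contrast between two block effects
#'
#' @param fit a [fit_day_model()] result.
#' @param block_a,block_b block labels; the estimate is
#'   `alpha_a - alpha_b` with a t-based confidence interval.
#' @param conf_level confidence level.
#' @return one-row tibble with `estimate`, `std_error`, `conf_low`,
#'   `conf_high`.
#' @export
block_contrast <- function(fit, block_a, block_b, conf_level = 0.95) {
  block_a <- as.character(block_a); block_b <- as.character(block_b)
  if (!block_a %in% fit$blocks || !block_b %in% fit$blocks)
    abort("unknown block label")
  cf <- coef(fit$model)
  v <- rep(0, length(cf)); names(v) <- names(cf)
  nm_a <- paste0("block", block_a); nm_b <- paste0("block", block_b)
  if (nm_a %in% names(v)) v[nm_a] <- 1
  if (nm_b %in% names(v)) v[nm_b] <- v[nm_b] - 1
  est <- sum(v * cf)
  se <- sqrt(drop(t(v) %*% suppressWarnings(vcov(fit$model)) %*% v))
  tcrit <- qt(1 - (1 - conf_level) / 2, fit$model$df.residual)
  tibble::tibble(
    day = fit$day, response = fit$response,
    block_a = block_a, block_b = block_b,
    estimate = est, std_error = se,
    conf_low = est - tcrit * se, conf_high = est + tcrit * se
  )
}

#' Genotype effect trajectories over days
#'
#' Fits the per-day model for every day present and collects the adjusted
#' genotype effects relative to the benchmark genotype (whose effect is
#' identically zero).
#'
#' @inheritParams fit_day_model
#' @param benchmark benchmark genotype label.
#' @param conf_level confidence level.
#' @return tibble of (day, genotype, estimate, std_error, conf_low,
#'   conf_high); days with aliased designs are skipped with a warning.
#' @export
genotype_series <- function(table, response, benchmark = NULL, conf_level = 0.95) {
  tt <- table[table$response == response, , drop = FALSE]
  if (length(unique(tt$genotype)) < 2)
    abort("at least 2 genotypes required for a genotype contrast")
  days <- sort(unique(tt$day))
  out <- purrr::map(days, function(d) {
    fit <- tryCatch(
      fit_day_model(table, d, response, benchmark_genotype = benchmark),
      error = function(e) {
        warn(paste0("day ", d, " skipped: ", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(fit)) return(NULL)
    td <- tidy(fit, conf_level = conf_level)
    td <- td[td$term_type == "genotype", , drop = FALSE]
    tibble::tibble(day = d, genotype = td$level, estimate = td$estimate,
                   std_error = td$std_error, conf_low = td$conf_low,
                   conf_high = td$conf_high)
  })
  dplyr::bind_rows(out)
}

#' Simulate a phenotype table with known block and genotype effects
#'
#' Builds a balanced design (genotypes assigned cyclically within blocks,
#' so block and genotype are never confounded), then draws
#' y = mu_t + alpha_i + gamma_g + N(0, sigma).
#'
#' @param seed RNG seed.
#' @param n_blocks,n_genotypes,plants_per_block design size.
#' @param days vector of imaging days.
#' @param block_effects,genotype_effects true effect vectors (first
#'   element must be 0, the reference level); defaults are evenly spread.
#' @param mu_t function of day giving the day intercept.
#' @param sigma residual standard deviation.
#' @param response response label.
#' @return list with `table` (the long phenotype tibble) and `truth`
#'   (the effect vectors used).
#' @export
simulate_phenotype_table <- function(seed, n_blocks = 4, n_genotypes = 6,
                                     plants_per_block = 6, days = 1:10,
                                     block_effects = NULL, genotype_effects = NULL,
                                     mu_t = function(t) 10 + 0.5 * t,
                                     sigma = 1, response = "pad") {
  if (is.null(block_effects)) block_effects <- c(0, seq_len(n_blocks - 1) * 0.8)
  if (is.null(genotype_effects)) genotype_effects <- c(0, seq_len(n_genotypes - 1) * 0.5)
  stopifnot(block_effects[1] == 0, genotype_effects[1] == 0)
  with_seed(seed, {
    design <- purrr::map_dfr(seq_len(n_blocks), function(i) {
      tibble::tibble(
        block = i, plant = seq_len(plants_per_block),
        genotype = ((i + seq_len(plants_per_block) - 2) %% n_genotypes) + 1
      )
    })
    design$plant_id <- sprintf("p%02d_%02d", design$block, design$plant)
    tab <- tidyr::crossing(design, day = days)
    tab$value <- mu_t(tab$day) + block_effects[tab$block] +
      genotype_effects[tab$genotype] + rnorm(nrow(tab), 0, sigma)
    tab$response <- response
    list(
      table = dplyr::select(tab, "plant_id", "block", "genotype", "day",
                            "response", "value"),
      truth = list(block_effects = block_effects,
                   genotype_effects = genotype_effects, sigma = sigma)
    )
  })
}
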