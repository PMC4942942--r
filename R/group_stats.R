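#' Two-way sex-by-age ANOVA
#'
#' Fixed-effects two-way ANOVA with interaction on one endpoint. Balanced
#' designs (the default study layout) use the orthogonal sums-of-squares
#' decomposition; unbalanced input falls back to Type II sums of squares
#' (via [car::Anova()]) with a warning. Cells with fewer than two
#' replicates, or empty cells, are errors. A zero error variance is
#' flagged and leaves p undefined.
#'
#' @param data data frame with columns `value`, `sex`, `age` (additional
#'   columns ignored).
#' @return object of class `oxbs_anova`: `table` (term, df, sumsq, meansq,
#'   statistic, p.value), `cell_means`, `ms_error`, `df_error`,
#'   `n_per_cell`, `balanced`.
#' @export
two_way_anova <- function(data) {
  stopifnot(all(c("value", "sex", "age") %in% names(data)))
  data <- data |>
    mutate(sex = factor(.data$sex), age = factor(.data$age))
  if (nlevels(data$sex) < 2 || nlevels(data$age) < 2) {
    abort("empty sex x age cell: both factors need at least two observed levels")
  }
  cells <- data |> count(.data$sex, .data$age, .drop = FALSE)
  if (any(cells$n == 0)) abort("empty sex x age cell")
  if (any(cells$n < 2)) abort("need >= 2 replicates per cell")
  balanced <- length(unique(cells$n)) == 1
  fit <- lm(value ~ sex * age, data = data)
  if (balanced) {
    # degenerate (zero-residual) layouts are flagged below; silence the
    # "essentially perfect fit" warning from anova.lm
    tab <- suppressWarnings(anova(fit))
  } else {
    warn("unbalanced design: using Type II sums of squares")
    tab <- car::Anova(fit, type = 2)
    # put columns in stats::anova order
    tab <- tab[, c("Df", "Sum Sq", "F value", "Pr(>F)")] |>
      (\(d) { d$`Mean Sq` <- d$`Sum Sq` / d$Df; d })() |>
      (\(d) d[, c("Df", "Sum Sq", "Mean Sq", "F value", "Pr(>F)")])()
  }
  tab_df <- tibble(term = rownames(tab),
                   df = tab$Df,
                   sumsq = tab$`Sum Sq`,
                   meansq = if ("Mean Sq" %in% colnames(tab)) tab$`Mean Sq`
                            else tab$`Sum Sq` / tab$Df,
                   statistic = tab$`F value`,
                   p.value = tab$`Pr(>F)`)
  err <- tab_df |> filter(.data$term == "Residuals")
  zero_var <- isTRUE(all.equal(err$meansq, 0)) || err$meansq == 0
  if (zero_var) {
    warn("zero error variance: F statistics undefined")
    tab_df$statistic[tab_df$term != "Residuals"] <- NA_real_
    tab_df$p.value[tab_df$term != "Residuals"] <- NA_real_
  }
  cell_means <- data |>
    group_by(.data$sex, .data$age) |>
    summarise(mean = mean(.data$value), n = n(), .groups = "drop")
  structure(list(table = tab_df,
                 cell_means = cell_means,
                 ms_error = err$meansq,
                 df_error = err$df,
                 n_per_cell = cells$n,
                 balanced = balanced,
                 data = data),
            class = "oxbs_anova")
}

#' @export
print.oxbs_anova <- function(x, ...) {
  cat("Two-way ANOVA (sex x age)", if (!x$balanced) "[Type II SS]", "\n")
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.oxbs_anova <- function(x, ...) x$table

#' @importFrom generics glance
#' @export
glance.oxbs_anova <- function(x, ...) {
  tibble(df_error = x$df_error, ms_error = x$ms_error,
         n = sum(x$n_per_cell), balanced = x$balanced)
}

#' Student-Newman-Keuls step-down post hoc test
#'
#' Step-down studentized-range procedure on a set of group means: means are
#' sorted; the comparison of the largest and smallest of a span of `r`
#' consecutive ordered means uses the `r`-mean critical value
#' `qtukey(1 - alpha, r, df_error)`; spans nested inside a non-significant
#' span are not subdivided (declared non-significant without testing).
#' Intended to follow a significant ANOVA factor.
#'
#' @param means named numeric vector of group means.
#' @param ms_error,df_error error mean square and df from the ANOVA.
#' @param n_per_group replicates per group; if unequal, the harmonic mean
#'   is used and the result is flagged.
#' @param alpha test level (default 0.05).
#' @return tibble per ordered pair: `group1`, `group2` (group1 has the
#'   smaller mean), `diff`, `range_r`, `q`, `q_crit`, `significant`,
#'   `blocked` (TRUE when the decision was forced by a wider
#'   non-significant span), `harmonic_n`.
#' @export
snk_posthoc <- function(means, ms_error, df_error, n_per_group, alpha = 0.05) {
  k <- length(means)
  stopifnot(k >= 2, !is.null(names(means)))
  harmonic <- length(unique(n_per_group)) > 1
  n_eff <- if (harmonic) {
    warn("unequal group sizes: using harmonic mean n")
    length(n_per_group) / sum(1 / n_per_group)
  } else n_per_group[1]
  ord <- order(means)
  m <- means[ord]
  se <- sqrt(ms_error / n_eff)
  res <- list()
  # iterate spans from widest to narrowest so containment blocking works
  nonsig <- matrix(FALSE, k, k)
  for (r in k:2) {
    for (i in 1:(k - r + 1)) {
      j <- i + r - 1
      blocked <- FALSE
      if (r < k) {
        # contained in a wider non-significant span?
        for (a in 1:i) for (b in j:k) {
          if ((b - a + 1) > r && nonsig[a, b]) blocked <- TRUE
        }
      }
      q <- (m[j] - m[i]) / se
      q_crit <- qtukey(1 - alpha, nmeans = r, df = df_error)
      sig <- !blocked && q >= q_crit
      if (!sig) nonsig[i, j] <- TRUE
      res[[length(res) + 1]] <- tibble(
        group1 = names(m)[i], group2 = names(m)[j],
        diff = unname(m[j] - m[i]), range_r = r,
        q = unname(q), q_crit = q_crit,
        significant = sig, blocked = blocked,
        harmonic_n = harmonic)
    }
  }
  bind_rows(res) |> arrange(desc(.data$range_r), .data$group1)
}

snk_from_anova <- function(fit, term, alpha = 0.05) {
  d <- fit$data
  g <- switch(term,
              sex = d$sex,
              age = d$age,
              `sex:age` = interaction(d$sex, d$age, sep = ":"))
  means <- tapply(d$value, g, mean)
  ns <- tapply(d$value, g, length)
  snk_posthoc(setNames(as.numeric(means), names(means)),
              fit$ms_error, fit$df_error, as.numeric(ns), alpha)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, name-preserving wrapper around `p.adjust(method = "BH")`:
#' monotone in rank and capped at 1.
#'
#' @param p vector of p values.
#' @return adjusted p values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Run an endpoint family: ANOVA + BH + SNK
#'
#' Fits the two-way sex-by-age ANOVA for every endpoint, applies
#' Benjamini-Hochberg correction to each ANOVA term within its declared
#' family (e.g. the five CGI region classes form one family, mirroring
#' per-panel correction), and runs SNK post hoc tests for terms whose
#' BH-adjusted p passes `alpha`.
#'
#' @param endpoints long tibble: `endpoint`, `sample_id`, `value`.
#' @param design [sample_design()] tibble.
#' @param families optional tibble `endpoint`, `family`; endpoints not
#'   listed form one `"default"` family.
#' @param alpha level for the SNK gate (default 0.05).
#' @return list of class `oxbs_family`: `anova` (endpoint, family, term,
#'   df, statistic, p.value, p.adj) and `snk` (pairwise decisions for
#'   passing terms).
#' @export
run_family <- function(endpoints, design, families = NULL, alpha = 0.05) {
  missing <- endpoints |>
    distinct(.data$endpoint) |>
    tidyr::expand_grid(sample_id = design$sample_id) |>
    anti_join(endpoints, by = c("endpoint", "sample_id"))
  if (nrow(missing)) {
    abort(paste0("endpoint ", missing$endpoint[1], " is missing sample ",
                 missing$sample_id[1]))
  }
  fam_of <- function(ep) {
    if (is.null(families)) return(rep("default", length(ep)))
    f <- families$family[match(ep, families$endpoint)]
    ifelse(is.na(f), "default", f)
  }
  fits <- endpoints |>
    inner_join(design, by = "sample_id") |>
    group_by(.data$endpoint) |>
    group_map(function(d, key) {
      fit <- two_way_anova(d)
      list(endpoint = key$endpoint, fit = fit)
    })
  anova_tab <- purrr::map_dfr(fits, function(f) {
    f$fit$table |>
      filter(.data$term != "Residuals") |>
      mutate(endpoint = f$endpoint, .before = 1)
  }) |>
    mutate(family = fam_of(.data$endpoint)) |>
    group_by(.data$family, .data$term) |>
    mutate(p.adj = bh_adjust(.data$p.value)) |>
    ungroup() |>
    select("endpoint", "family", "term", "df", "sumsq", "meansq",
           "statistic", "p.value", "p.adj")
  passing <- anova_tab |> filter(!is.na(.data$p.adj), .data$p.adj < alpha)
  snk <- purrr::map_dfr(seq_len(nrow(passing)), function(i) {
    row <- passing[i, ]
    fit <- purrr::detect(fits, \(f) f$endpoint == row$endpoint)$fit
    snk_from_anova(fit, row$term, alpha) |>
      mutate(endpoint = row$endpoint, term = row$term, .before = 1)
  })
  structure(list(anova = anova_tab, snk = snk), class = "oxbs_family")
}

#' @export
print.oxbs_family <- function(x, ...) {
  cat("<oxbs_family> ", nrow(x$anova), " endpoint x term rows; ",
      nrow(x$snk), " SNK comparisons\n", sep = "")
  print(x$anova)
  invisible(x)
}
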