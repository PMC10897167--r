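# Factorial ANOVA, Fisher's LSD post hocs and Bonferroni alpha families.

check_cells <- function(data, factors, min_n = 2L) {
  tab <- table(data[factors])
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)
    lbl <- paste(mapply(function(d, i) dimnames(tab)[[d]][i],
                        seq_along(factors), empty[1L, ]), collapse = " x ")
    stop("empty design cell: ", lbl)
  }
  if (any(tab < min_n)) {
    stop("every design cell needs at least ", min_n, " observations")
  }
  invisible(tab)
}

anova_table_from_df <- function(tab, terms) {
  out <- data.frame(term = terms,
                    df = tab$Df,
                    sum_sq = tab$`Sum Sq`,
                    mean_sq = tab$`Sum Sq` / tab$Df,
                    F = if ("F value" %in% names(tab)) tab$`F value` else NA,
                    p = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)` else NA)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Decomposes an outcome by two crossed factors (age and genotype in the
#' study design) plus their interaction.  Balanced designs use the exact
#' (Type I = Type III) sequential decomposition; unbalanced designs use
#' Type II sums of squares via [car::Anova()].
#'
#' @param data Data frame with the outcome and factor columns.
#' @param factors Character vector of the two factor column names.
#' @param response Outcome column name.
#' @return Object of class `anova_table`: data.frame with `term`, `df`,
#'   `sum_sq`, `mean_sq`, `F`, `p` rows for both factors, the interaction
#'   and residuals; attribute `fit` holds the underlying `lm`.
#' @export
two_way_anova <- function(data, factors = c("age", "genotype"),
                          response = "value") {
  stopifnot(length(factors) == 2L, all(factors %in% names(data)),
            response %in% names(data))
  for (f in factors) data[[f]] <- factor(data[[f]])
  if (any(vapply(data[factors], nlevels, integer(1L)) < 2L)) {
    stop("each factor needs at least 2 levels")
  }
  check_cells(data, factors)
  form <- stats::as.formula(paste(response, "~", factors[1L], "*", factors[2L]))
  fit <- stats::lm(form, data = data)
  balanced <- length(unique(table(data[factors]))) == 1L
  if (balanced) {
    tab <- as.data.frame(stats::anova(fit))
  } else {
    a2 <- as.data.frame(car::Anova(fit, type = 2))
    # reorder columns to the stats::anova layout
    tab <- data.frame(Df = a2$Df, `Sum Sq` = a2$`Sum Sq`,
                      `F value` = a2$`F value`, `Pr(>F)` = a2$`Pr(>F)`,
                      check.names = FALSE)
    rownames(tab) <- rownames(a2)
  }
  terms <- c(factors[1L], factors[2L],
             paste0(factors[1L], ":", factors[2L]), "Residuals")
  tab <- tab[match(terms, rownames(tab)), , drop = FALSE]
  out <- anova_table_from_df(tab, terms)
  attr(out, "fit") <- fit
  attr(out, "type") <- if (balanced) "I (balanced)" else "II"
  out
}

#' One-way fixed-effects ANOVA
#'
#' @param data Data frame with the outcome and factor column.
#' @param factor_name Grouping factor column name.
#' @param response Outcome column name.
#' @return An `anova_table` with the factor and residual rows.
#' @export
one_way_anova <- function(data, factor_name = "age", response = "value") {
  stopifnot(factor_name %in% names(data), response %in% names(data))
  data[[factor_name]] <- factor(data[[factor_name]])
  if (nlevels(data[[factor_name]]) < 2L) {
    stop("need at least 2 groups for a one-way ANOVA")
  }
  check_cells(data, factor_name)
  form <- stats::as.formula(paste(response, "~", factor_name))
  fit <- stats::lm(form, data = data)
  tab <- as.data.frame(stats::anova(fit))
  out <- anova_table_from_df(tab, c(factor_name, "Residuals"))
  attr(out, "fit") <- fit
  out
}

#' Fisher's LSD pairwise comparison of two design cells
#'
#' Unprotected pairwise t-test using the ANOVA residual mean square:
#' `t = (m1 - m2) / sqrt(MSE (1/n1 + 1/n2))` with the residual df; meant to
#' be gated by an a priori Bonferroni-corrected alpha from
#' [bonferroni_alpha()].
#'
#' @param anova An `anova_table` from [two_way_anova()] or
#'   [one_way_anova()].
#' @param data The data the ANOVA was fitted on.
#' @param cell_a,cell_b Named character vectors identifying the two cells,
#'   e.g. `c(age = "4mo", genotype = "Ctrl")`.
#' @param response Outcome column name.
#' @return List with `diff`, `t`, `df`, `p_value`, `n` (per-cell counts).
#' @export
fisher_lsd <- function(anova, data, cell_a, cell_b, response = "value") {
  res_row <- anova[anova$term == "Residuals", ]
  mse <- res_row$mean_sq
  df <- res_row$df
  pick <- function(cell) {
    keep <- rep(TRUE, nrow(data))
    for (f in names(cell)) {
      if (!f %in% names(data)) stop("unknown factor '", f, "'")
      keep <- keep & as.character(data[[f]]) == cell[[f]]
    }
    v <- data[[response]][keep]
    if (length(v) == 0L) {
      stop("cell not found in the design: ",
           paste(names(cell), cell, sep = "=", collapse = ", "))
    }
    v
  }
  va <- pick(cell_a); vb <- pick(cell_b)
  diff <- mean(va) - mean(vb)
  se <- sqrt(mse * (1 / length(va) + 1 / length(vb)))
  t <- diff / se
  list(diff = diff, t = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df),
       n = c(length(va), length(vb)))
}

#' Bonferroni-corrected alpha for a comparison family
#'
#' `alpha_corrected = family_alpha / m`, reported exactly and rounded
#' (half-even) to 3 decimals, matching the printed convention of corrected
#' thresholds such as 0.0125 (m = 4), 0.008 (m = 6) and 0.007 (m = 7).
#'
#' @param m Number of comparisons in the family (>= 1).
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return List with `alpha` (exact) and `printed` (3-dp rounding).
#' @export
bonferroni_alpha <- function(m, family_alpha = 0.05) {
  if (length(m) != 1L || !is.finite(m) || m < 1) {
    stop("'m' must be a single number >= 1")
  }
  a <- family_alpha / m
  list(alpha = a, printed = round(a, 3))
}
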