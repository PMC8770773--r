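#' @title Repeated-measures behavioural statistics
#' @description
#' The behavioural analyses are 2x2 within-participant ANOVAs (factors
#' CS-Type: CS+/CS-, and Instruction: view/imagine or view/regulate) with
#' generalized eta-squared effect sizes, plus paired and one-sample t-tests
#' with Cohen's d. Generalized eta-squared uses all subject-related error
#' terms in its denominator (Olejnik-Algina / Bakeman convention), making it
#' comparable across designs; with two-level factors sphericity is not an
#' issue and no correction is applied.
#' @name behavioral_stats
NULL

#' Two-by-two repeated-measures ANOVA with generalized eta-squared
#'
#' @param data Data frame with one value per participant per cell.
#' @param participant,a,b,value Column names: participant identifier, the
#'   two within-participant factors (each with exactly 2 levels), and the
#'   response. Duplicate cells are averaged; participants with missing cells
#'   after that are dropped listwise.
#' @return Data frame of class `anova_result` with rows for the two main
#'   effects and the interaction: `effect`, `F`, `df_num`, `df_den`, `p`,
#'   `eta_G_sq`. `df_den` is the number of complete participants minus 1.
#' @examples
#' d <- expand.grid(participant = 1:6, cs = c("CSplus", "CSminus"),
#'                  instruction = c("view", "imagine"))
#' d$value <- rnorm(nrow(d)) + (d$cs == "CSplus") * (d$instruction == "view")
#' rm_anova_2x2(d, "participant", "cs", "instruction", "value")
#' @export
rm_anova_2x2 <- function(data, participant = "participant", a = "cs_type",
                         b = "instruction", value = "value") {
  stopifnot(all(c(participant, a, b, value) %in% names(data)))
  df <- data.frame(
    pid = factor(data[[participant]]),
    A = factor(data[[a]]), B = factor(data[[b]]),
    y = as.numeric(data[[value]])
  )
  if (nlevels(df$A) != 2 || nlevels(df$B) != 2) {
    stop_config("both factors must have exactly 2 levels")
  }
  df <- stats::aggregate(y ~ pid + A + B, df, mean)
  complete <- names(which(table(df$pid) == 4))
  df <- df[df$pid %in% complete, , drop = FALSE]
  df$pid <- droplevels(df$pid)
  n <- nlevels(df$pid)
  if (n < 2) stop_config("need at least 2 complete participants")

  fit <- stats::aov(y ~ A * B + Error(pid / (A * B)), data = df)
  sm <- summary(fit)
  ss <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    if (is.na(i)) 0 else tab[i, "Sum Sq"]
  }
  ss_sub <- ss("Error: pid", "Residuals")
  comp <- list(
    list(effect = a, eff = ss("Error: pid:A", "A"),
         err = ss("Error: pid:A", "Residuals")),
    list(effect = b, eff = ss("Error: pid:B", "B"),
         err = ss("Error: pid:B", "Residuals")),
    list(effect = paste0(a, ":", b), eff = ss("Error: pid:A:B", "A:B"),
         err = ss("Error: pid:A:B", "Residuals"))
  )
  err_all <- ss_sub + sum(vapply(comp, `[[`, 0.0, "err"))
  scale_tol <- 1e-12 * max(1, sum(df$y^2))
  out <- do.call(rbind, lapply(comp, function(cm) {
    df_den <- n - 1
    if (cm$eff < scale_tol) {
      f <- 0; p <- 1
    } else if (cm$err < scale_tol) {
      f <- Inf; p <- 0
    } else {
      f <- (cm$eff / 1) / (cm$err / df_den)
      p <- stats::pf(f, 1, df_den, lower.tail = FALSE)
    }
    eta <- if (cm$eff < scale_tol) 0 else cm$eff / (cm$eff + err_all)
    data.frame(effect = cm$effect, F = f, df_num = 1L, df_den = df_den,
               p = p, eta_G_sq = eta, stringsAsFactors = FALSE)
  }))
  class(out) <- c("anova_result", class(out))
  out
}

finish_t <- function(t_stat, df, tail, d, flag = FALSE) {
  p <- switch(tail,
    two.sided = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
    greater = stats::pt(t_stat, df, lower.tail = FALSE),
    less = stats::pt(t_stat, df)
  )
  structure(list(t = t_stat, df = df, p = p, tail = tail, cohen_d = d,
                 degenerate = flag),
            class = "t_test_result")
}

#' Paired t-test with Cohen's d
#'
#' Cohen's d for paired contrasts defaults to the mean difference divided by
#' the standard deviation of the differences; `d_method = "pooled_sd"`
#' divides by the pooled SD of the two conditions instead. One-tailed tests
#' (e.g. the directional CS+ > CS- SCR hypothesis) use `tail = "greater"`.
#'
#' @param x,y Paired numeric vectors (length >= 2).
#' @param tail `"two.sided"` (default), `"greater"` (x > y), or `"less"`.
#' @param d_method Cohen's d convention.
#' @return An object of class `t_test_result`: `t`, `df`, `p`, `tail`,
#'   `cohen_d`, and a `degenerate` flag set when the differences have zero
#'   variance (p is then reported at the machine bound).
#' @export
paired_t <- function(x, y, tail = c("two.sided", "greater", "less"),
                     d_method = c("difference_sd", "pooled_sd")) {
  tail <- match.arg(tail)
  d_method <- match.arg(d_method)
  stopifnot(length(x) == length(y), length(x) >= 2)
  dd <- x - y
  n <- length(dd)
  sd_d <- stats::sd(dd)
  if (sd_d == 0) {
    if (mean(dd) == 0) {
      return(finish_t(0, n - 1, tail, 0))
    }
    p <- .Machine$double.xmin
    res <- finish_t(sign(mean(dd)) * Inf, n - 1, tail, Inf * sign(mean(dd)),
                    flag = TRUE)
    res$p <- if (tail == "less" && mean(dd) > 0) 1
             else if (tail == "greater" && mean(dd) < 0) 1 else p
    return(res)
  }
  t_stat <- mean(dd) / (sd_d / sqrt(n))
  d <- switch(d_method,
    difference_sd = mean(dd) / sd_d,
    pooled_sd = mean(dd) / sqrt((stats::var(x) + stats::var(y)) / 2)
  )
  finish_t(t_stat, n - 1, tail, d)
}

#' One-sample t-test with Cohen's d
#'
#' Used, for instance, to test imagery vividness ratings against the scale
#' floor of 1 ("non-existent").
#'
#' @param x Numeric vector (length >= 2).
#' @param mu Null value.
#' @inheritParams paired_t
#' @return An object of class `t_test_result`.
#' @export
one_sample_t <- function(x, mu = 0, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(length(x) >= 2)
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) {
    if (mean(x) == mu) return(finish_t(0, n - 1, tail, 0))
    res <- finish_t(sign(mean(x) - mu) * Inf, n - 1, tail,
                    Inf * sign(mean(x) - mu), flag = TRUE)
    res$p <- if ((tail == "less" && mean(x) > mu) ||
                 (tail == "greater" && mean(x) < mu)) 1 else .Machine$double.xmin
    return(res)
  }
  t_stat <- (mean(x) - mu) / (s / sqrt(n))
  finish_t(t_stat, n - 1, tail, (mean(x) - mu) / s)
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> t(%d) = %.3f, p = %.4g (%s), d = %.3f\n",
              x$df, x$t, x$p, x$tail, x$cohen_d))
  invisible(x)
}
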