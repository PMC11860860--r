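#' Net ammonia relative to blank fermenters
#'
#' Ammonia in batch cultures partly reflects background fermentation of the
#' inoculum itself, so NH3 is reported as the difference between the
#' concentration in a test fermenter and the mean concentration in the
#' blank fermenters at the same time point. Negative differences are
#' meaningful (net incorporation of N into microbial protein) and are
#' preserved.
#'
#' @param test Tidy metabolite table with columns `time_h`, `analyte`,
#'   `value` (and any id columns, kept); only `NH3` rows are adjusted, all
#'   rows are returned.
#' @param blanks Tidy metabolite table of blank fermenters containing `NH3`
#'   at every time point present in `test`.
#' @return `test` with NH3 values replaced by test-minus-mean-blank
#'   differences (mmol/L).
#' @export
nh3_difference <- function(test, blanks) {
  test <- as_tibble(test)
  blanks <- as_tibble(blanks)
  bl <- blanks %>%
    filter(.data$analyte == "NH3") %>%
    group_by(.data$time_h) %>%
    summarise(blank_nh3 = mean(.data$value), .groups = "drop")
  need <- unique(test$time_h[test$analyte == "NH3"])
  missing_t <- setdiff(need, bl$time_h)
  if (length(missing_t) > 0)
    abort(sprintf("No blank NH3 at time point(s): %s",
                  paste(sort(missing_t), collapse = ", ")))
  test %>%
    left_join(bl, by = "time_h") %>%
    mutate(value = ifelse(.data$analyte == "NH3",
                          .data$value - .data$blank_nh3, .data$value)) %>%
    select(-"blank_nh3")
}

#' Acetate-to-propionate ratio per fermenter
#'
#' Appends the C2:C3 ratio (acetic over propionic acid) as a new analyte,
#' computed per fermenter and time point before any downstream averaging —
#' the mean of per-fermenter ratios, not the ratio of means. A zero
#' propionic acid concentration gives a missing ratio rather than infinity.
#'
#' @param data Tidy metabolite table with `acetic` and `propionic` rows
#'   sharing id columns (`run`, `fermenter`, `variant` where present) and
#'   `time_h`.
#' @return `data` with additional rows `analyte = "C2:C3"`.
#' @export
c2_c3_ratio <- function(data) {
  data <- as_tibble(data)
  ids <- intersect(c("run", "fermenter", "variant", "medium", "time_h"),
                   names(data))
  wide <- data %>%
    filter(.data$analyte %in% c("acetic", "propionic")) %>%
    tidyr::pivot_wider(id_cols = dplyr::all_of(ids),
                       names_from = "analyte", values_from = "value")
  if (!all(c("acetic", "propionic") %in% names(wide)))
    abort("Both acetic and propionic acid are required for the C2:C3 ratio.")
  ratios <- wide %>%
    mutate(value = ifelse(.data$propionic == 0, NA_real_,
                          .data$acetic / .data$propionic),
           analyte = "C2:C3") %>%
    select(-"acetic", -"propionic")
  if (any(is.na(ratios$value)))
    warn("Zero propionic acid: C2:C3 flagged missing for some fermenters.")
  bind_rows(data, ratios)
}

#' Pairwise correlation table at one time point
#'
#' Computes Pearson, Spearman or Kendall correlations between all analyte
#' pairs measured on the same fermenters at a single incubation time point
#' (24 h in the study workflow, because toxin levels beyond 24 h were
#' sometimes below the measurement range). Spearman is computed as Pearson
#' on average ranks with a t-approximation p-value; Kendall is the
#' tie-corrected tau-b with a normal-approximation p-value; Pearson uses the
#' exact t test. Observations are paired fermenter-wise and handled
#' pairwise-complete. A constant analyte has undefined correlations,
#' reported as `NA`.
#'
#' @param data Tidy metabolite table with `fermenter` (and optionally `run`)
#'   id columns, `time_h`, `analyte`, `value`.
#' @param time_h Time point to analyse (default 24).
#' @param method One or more of `"pearson"`, `"spearman"`, `"kendall"`.
#' @param min_n Minimum paired observations per pair (default 3).
#' @return A tibble `(method, var1, var2, r, p, n)` over unordered analyte
#'   pairs including the diagonal (`r = 1`, `p = NA`).
#' @examples
#' d <- tidyr::expand_grid(fermenter = 1:6, analyte = c("x", "y"))
#' d$time_h <- 24
#' d$value <- c(rbind(1:6, (1:6)^2))
#' correlation_matrix(d, method = "spearman")
#' @export
correlation_matrix <- function(data, time_h = 24,
                               method = c("pearson", "spearman", "kendall"),
                               min_n = 3) {
  method <- match.arg(method, several.ok = TRUE)
  data <- as_tibble(data)
  ids <- intersect(c("run", "fermenter"), names(data))
  if (length(ids) == 0) abort("`data` needs a `fermenter` id column.")
  snap <- data %>% filter(.data$time_h == !!time_h)
  if (nrow(snap) == 0) abort(sprintf("No observations at time %g h.", time_h))
  wide <- snap %>%
    tidyr::pivot_wider(id_cols = dplyr::all_of(ids),
                       names_from = "analyte", values_from = "value",
                       values_fn = mean)
  vars <- setdiff(names(wide), ids)
  pairs <- expand.grid(i = seq_along(vars), j = seq_along(vars)) %>%
    filter(.data$i <= .data$j)
  out <- purrr::map_dfr(method, function(m) {
    purrr::pmap_dfr(pairs, function(i, j) {
      x <- wide[[vars[i]]]; y <- wide[[vars[j]]]
      ok <- complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      if (i == j)
        return(tibble(method = m, var1 = vars[i], var2 = vars[j],
                      r = 1, p = NA_real_, n = n))
      if (n < min_n || sd(x) == 0 || sd(y) == 0)
        return(tibble(method = m, var1 = vars[i], var2 = vars[j],
                      r = NA_real_, p = NA_real_, n = n))
      res <- cor_pair(x, y, m)
      tibble(method = m, var1 = vars[i], var2 = vars[j],
             r = res$r, p = res$p, n = n)
    })
  })
  as_tibble(out)
}

cor_pair <- function(x, y, method) {
  switch(method,
    pearson = {
      ct <- cor.test(x, y, method = "pearson")
      list(r = unname(ct$estimate), p = ct$p.value)
    },
    spearman = {
      # Pearson on average ranks; p from the t approximation
      ct <- cor.test(rank(x), rank(y), method = "pearson")
      list(r = unname(ct$estimate), p = ct$p.value)
    },
    kendall = {
      ct <- suppressWarnings(
        cor.test(x, y, method = "kendall", exact = FALSE))
      list(r = unname(ct$estimate), p = ct$p.value)
    }
  )
}

#' Star-annotated wide correlation table
#'
#' Reshapes the long output of [correlation_matrix()] into a wide table
#' with one row per `var1` and the correlation of each pair annotated with
#' the conventional significance stars (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, no multiplicity correction).
#'
#' @param cor_table Output of [correlation_matrix()] for a single method.
#' @param digits Digits for the printed coefficients (default 2).
#' @return A wide tibble of character cells like `"-0.86 ***"`.
#' @export
correlation_wide <- function(cor_table, digits = 2) {
  if (length(unique(cor_table$method)) > 1)
    abort("`cor_table` must hold a single method; filter first.")
  stars <- function(p) dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ " ***",
    p < 0.01 ~ " **",
    p < 0.05 ~ " *",
    TRUE ~ ""
  )
  full <- bind_rows(
    cor_table,
    cor_table %>% filter(.data$var1 != .data$var2) %>%
      rename(var1 = "var2", var2 = "var1")
  ) %>%
    mutate(cell = ifelse(is.na(.data$r), "",
                         paste0(formatC(.data$r, digits = digits,
                                        format = "f"), stars(.data$p))))
  full %>%
    select("var1", "var2", "cell") %>%
    tidyr::pivot_wider(names_from = "var2", values_from = "cell")
}
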