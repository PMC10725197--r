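# Formatting helpers shared by print methods and the Table-1 renderer.

fmt_percent <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", formatC(100 * x, format = "f", digits = digits))
}

fmt_percent_ci <- function(ci, digits = 2) {
  paste0(fmt_percent(ci$lower, digits), "-", fmt_percent(ci$upper, digits))
}

fmt_denominator <- function(n) {
  # format = "f" rather than "d": denominators can exceed integer range
  ifelse(is.na(n), "1/NA",
         paste0("1/", formatC(round_half_up(n), format = "f", digits = 0,
                              big.mark = ",")))
}

fmt_denominator_ci <- function(pair) {
  paste0(fmt_denominator(pair[[1L]]), "-", fmt_denominator(pair[[2L]]))
}

#' Render carrier estimates as a publication-style incidence table
#'
#' Formats a list of fitted estimates into the familiar carrier-frequency /
#' estimated-incidence table: rows grouped by population with one row per
#' scheme, carrier frequency as a 2-decimal percent with its interval in
#' parentheses, and incidence as a comma-grouped `1/n` denominator (`1/NA`
#' for zero-count cohorts).
#'
#' @param estimates Non-empty list of `carrier_estimate` objects (see
#'   [carrier_fit()]).
#' @return Character vector of aligned text lines (one header plus one line
#'   per estimate), with a `data` attribute carrying the underlying data
#'   frame.
#' @export
render_table1 <- function(estimates) {
  if (inherits(estimates, "carrier_estimate")) estimates <- list(estimates)
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, NA, "carrier_estimate")))
  df <- do.call(rbind, lapply(estimates, function(e) {
    co <- e$cohort
    data.frame(
      population = co$label,
      scheme = co$scheme,
      n_individuals = co$n_individuals,
      alleles = co$disease_allele_count,
      carrier_frequency_pct = round(100 * e$carrier_frequency, 2),
      cf_display = sprintf("%s (%s)", fmt_percent(e$carrier_frequency),
                           fmt_percent_ci(e$cf_ci)),
      incidence_denominator = e$incidence_denominator,
      incidence_display = sprintf("%s (%s)",
                                  fmt_denominator(e$incidence_denominator),
                                  fmt_denominator_ci(e$incidence_denominator_ci)),
      stringsAsFactors = FALSE)
  }))
  df <- df[order(match(df$population, unique(df$population)),
                 match(df$scheme, c("acmg", "clinvar", "hgmd"))), ,
           drop = FALSE]
  rownames(df) <- NULL
  cols <- c("population", "scheme", "alleles", "cf_display", "incidence_display")
  header <- c("Population", "Scheme", "Alleles",
              "Carrier frequency % (95% CI)", "Estimated incidence (95% CI)")
  cells <- rbind(header, as.matrix(format(df[, cols])))
  widths <- apply(nchar(cells), 2L, max)
  lines <- apply(cells, 1L, function(r)
    paste(mapply(formatC, r, width = widths, MoreArgs = list(flag = "-")),
          collapse = "  "))
  lines <- trimws(lines, which = "right")
  attr(lines, "data") <- df
  lines
}
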