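#' Segregation-ratio summary and penetrance estimate
#'
#' Under an autosomal dominant model, half the offspring of a carrier x clear
#' mating inherit the disease allele, so with full penetrance half should be
#' affected. The observed affected fraction among such offspring therefore
#' estimates penetrance/2, and `penetrance = min(1, 2 x fraction)`. The
#' summary is restricted to matings of exactly one carrier with one
#' clear-by-pedigree mate; carrier x carrier matings are excluded (expected
#' carrier fraction is not 1/2 and the fate of disease homozygotes is
#' unknown).
#'
#' Carriers inferred through their affected progeny ("several mates" rule)
#' are ascertained through the very offspring being counted, which biases the
#' fraction upward at low penetrance. `carrier_basis = "obligate"` restricts
#' to affected parents — whose carrier status is known independently of
#' their offspring — giving an ascertainment-free estimate; the default
#' `"any"` mirrors the field practice of pooling all deduced carriers.
#'
#' @param ped a [pedigree()]
#' @param carriers an [assign_carriers()] result
#' @param risk a [classify_risk()] result
#' @param carrier_basis `"any"` (obligate + inferred carriers) or
#'   `"obligate"` (affected parents only)
#' @param conf_level confidence level for the Wilson score interval
#' @return list of class `segregation_summary`:
#'   `n_offspring`, `n_affected`, `observed_fraction`,
#'   `expected_carrier_fraction` (0.5), `penetrance_estimate`, `ci_low`,
#'   `ci_high`, `n_matings`. With no qualifying matings all statistics are
#'   `NA` and `n_offspring = 0`.
#' @export
segregation_summary <- function(ped, carriers, risk,
                                carrier_basis = c("any", "obligate"),
                                conf_level = 0.95) {
  carrier_basis <- match.arg(carrier_basis)
  df <- ped_df(ped)
  cmap <- stats::setNames(carriers$status, carriers$id)
  prov <- stats::setNames(carriers$provenance, carriers$id)
  is_c <- function(x) {
    ok <- !is.na(cmap[x]) & cmap[x] %in% c("obligate_carrier", "inferred_carrier")
    if (carrier_basis == "obligate")
      ok <- ok & cmap[x] == "obligate_carrier" & prov[x] == "affected"
    unname(ok)
  }
  is_clear <- function(x) {
    r <- cmap[x]
    !is.na(r) & r == "clear"
  }
  off <- df[!is.na(df$sire) & !is.na(df$dam), , drop = FALSE]
  qual <- (is_c(off$sire) & is_clear(off$dam)) |
    (is_c(off$dam) & is_clear(off$sire))
  off <- off[qual, , drop = FALSE]
  n <- nrow(off)
  if (n == 0) {
    return(structure(list(n_offspring = 0L, n_affected = 0L,
                          observed_fraction = NA_real_,
                          expected_carrier_fraction = 0.5,
                          penetrance_estimate = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          n_matings = 0L),
                     class = "segregation_summary"))
  }
  k <- sum(off$affection == "affected")
  frac <- k / n
  ci <- wilson_ci(k, n, conf_level)
  structure(list(
    n_offspring = n, n_affected = k, observed_fraction = frac,
    expected_carrier_fraction = 0.5,
    penetrance_estimate = min(1, 2 * frac),
    ci_low = min(1, 2 * ci[1]), ci_high = min(1, 2 * ci[2]),
    n_matings = length(unique(paste(off$sire, off$dam)))),
    class = "segregation_summary")
}

#' @export
print.segregation_summary <- function(x, ...) {
  cat(sprintf("<segregation_summary> %d offspring of carrier x clear matings (%d matings)\n",
              x$n_offspring, x$n_matings))
  if (x$n_offspring > 0)
    cat(sprintf("  affected: %d (fraction %.3f); penetrance estimate %.3f [%.3f, %.3f]\n",
                x$n_affected, x$observed_fraction, x$penetrance_estimate,
                x$ci_low, x$ci_high))
  invisible(x)
}

# Wilson score interval for a binomial proportion; behaved at small counts
wilson_ci <- function(k, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' How often do transmitters themselves express the disease?
#'
#' Descriptive support for the low-penetrance argument: transmitting parents
#' were seldom found to develop the disease themselves. Reports the fraction
#' of transmitter dogs recorded affected, with their onset ages.
#'
#' @param ped a [pedigree()]
#' @param transmitters an [identify_transmitters()] result
#' @return list: `n_transmitters`, `n_affected`, `fraction_affected`,
#'   `onset_ages` (of affected transmitters)
#' @export
transmitter_expression_report <- function(ped, transmitters) {
  df <- ped_df(ped)
  tr <- transmitters$id[transmitters$is_transmitter]
  # restrict to producers: dogs called transmitter through offspring, or
  # affected dogs that also produced affected offspring
  tr <- transmitters$id[transmitters$is_transmitter &
                          transmitters$n_affected_offspring > 0]
  sel <- df$id %in% tr
  aff <- df$affection[sel] == "affected"
  list(n_transmitters = sum(sel),
       n_affected = sum(aff),
       fraction_affected = if (any(sel)) mean(aff) else NA_real_,
       onset_ages = df$onset_age[sel][aff])
}
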