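#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-position nucleotide frequencies of a barcode model
#'
#' @param x A `barcode_freq_model`.
#' @param ... Unused.
#' @return Tibble `position`, `nucleotide`, `freq`.
#' @method tidy barcode_freq_model
#' @export
tidy.barcode_freq_model <- function(x, ...) {
  x$f
}

#' One-row summary of a barcode frequency model
#'
#' @param x A `barcode_freq_model`.
#' @param ... Unused.
#' @return Tibble `n_barcodes`, `n_excluded`, `n_zero_p`, `free_parameters`.
#' @method glance barcode_freq_model
#' @export
glance.barcode_freq_model <- function(x, ...) {
  tibble::tibble(
    n_barcodes = nrow(x$p),
    n_excluded = length(x$excluded),
    n_zero_p = sum(x$p$zero_p),
    free_parameters = free_parameters(x$design)
  )
}

#' Per-barcode expected collisions of a solved estimate
#'
#' @param x A `collision_estimate`.
#' @param ... Unused.
#' @return Tibble `barcode`, `p`, `C`.
#' @method tidy collision_estimate
#' @export
tidy.collision_estimate <- function(x, ...) {
  x$collisions
}

#' One-row summary of a collision estimate
#'
#' @param x A `collision_estimate`.
#' @param ... Unused.
#' @return Tibble `n_obs`, `N`, `total_collisions`, `collision_fraction`.
#' @method glance collision_estimate
#' @export
glance.collision_estimate <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, N = x$N, total_collisions = x$total_collisions,
    collision_fraction = if (x$N > 0) x$total_collisions / x$N else 0
  )
}

#' Tidy a pipeline run into its per-variant summary
#'
#' @param x A `tubaseq_run`.
#' @param ... Unused.
#' @return The `variant_summary` tibble.
#' @method tidy tubaseq_run
#' @export
tidy.tubaseq_run <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' One-row summary of a pipeline run
#'
#' @param x A `tubaseq_run`.
#' @param ... Unused.
#' @return Tibble with sample/call counts, mean error rate, mean shadow
#'   fraction and mean expected collision fraction.
#' @method glance tubaseq_run
#' @export
glance.tubaseq_run <- function(x, ...) {
  coll <- x$collision_estimates
  tibble::tibble(
    n_samples = length(unique(x$calls$sample)),
    n_calls = nrow(x$calls),
    n_above_cutoff = nrow(x$kept),
    mean_error_rate = mean(x$error_rates),
    mean_shadow_fraction = mean(x$shadow_fractions),
    mean_collision_fraction =
      sum(coll$expected_collisions) / max(1, sum(coll$N))
  )
}
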