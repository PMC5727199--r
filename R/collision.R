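#' Fit the independent per-position barcode frequency model
#'
#' Most reproducible variation between barcode frequencies in the plasmid
#' pool comes from independent nucleotide-concentration skew at each wobble
#' position. The model estimates the read-weighted frequency `f[b, n]` of
#' nucleotide n at each wobble position b and predicts every barcode's pool
#' probability as the product over positions, renormalized over the barcode
#' space — 21 free parameters for the default design.
#'
#' @param pool Plasmid pool tibble (`barcode`, `reads`; the variant column is
#'   ignored — barcode synthesis is shared across variants).
#' @param design A [kras_design()].
#' @return An object of class `barcode_freq_model`: list with `f` (tibble
#'   position, nucleotide, freq), `p` (tibble barcode, p over the full
#'   space), `excluded` (character), `design`. Barcodes containing a
#'   never-observed nucleotide get p = 0 and are flagged (`zero_p`).
#' @export
fit_barcode_frequencies <- function(pool, design = kras_design()) {
  stopifnot(nrow(pool) > 0)
  k <- length(design$wobble_pos)
  chars <- seq_matrix(pool$barcode)
  stopifnot(ncol(chars) == k)

  f <- dplyr::bind_rows(lapply(seq_len(k), function(b) {
    alpha <- design$wobble_alphabets[[b]]
    w <- vapply(alpha, function(nt) sum(pool$reads[chars[, b] == nt]),
                numeric(1))
    tibble::tibble(position = b, nucleotide = alpha,
                   freq = unname(w / sum(w)))
  }))

  space <- enumerate_barcodes(design)
  space_chars <- seq_matrix(space)
  logp <- rep(0, length(space))
  for (b in seq_len(k)) {
    fb <- f[f$position == b, ]
    logp <- logp + log(fb$freq[match(space_chars[, b], fb$nucleotide)])
  }
  p <- exp(logp)
  p <- p / sum(p)

  structure(
    list(
      f = f,
      p = tibble::tibble(barcode = space, p = p, zero_p = p == 0),
      excluded = character(),
      design = design
    ),
    class = "barcode_freq_model"
  )
}

#' @export
print.barcode_freq_model <- function(x, ...) {
  cat("<barcode_freq_model> ", nrow(x$p), " barcodes; ",
      free_parameters(x$design), " free parameters; ",
      length(x$excluded), " excluded\n", sep = "")
  invisible(x)
}

# probabilities over retained (non-excluded, p > 0) barcodes, renormalized
retained_p <- function(model) {
  keep <- !(model$p$barcode %in% model$excluded) & model$p$p > 0
  p <- model$p$p[keep]
  stats::setNames(p / sum(p), model$p$barcode[keep])
}

#' Exclude the most over-represented barcodes and renormalize
#'
#' Residual over-representation beyond the per-position frequency model is
#' handled by discarding the top `fraction` of observed barcodes ranked by
#' observed count divided by modeled probability (ties broken
#' lexicographically), then renormalizing the retained probabilities to
#' sum 1. The exclusion is computed from the plasmid-library sequencing, not
#' from the mouse samples.
#'
#' @param model A `barcode_freq_model`.
#' @param pool Observed plasmid pool tibble (`barcode`, `reads`).
#' @param fraction Fraction of observed barcodes to exclude (default 0.10).
#' @return The model with `excluded` filled in.
#' @export
exclude_frequent_barcodes <- function(model, pool, fraction = 0.10) {
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  if (fraction == 0) return(model)
  obs <- dplyr::summarise(dplyr::group_by(pool, .data$barcode),
                          reads = sum(.data$reads), .groups = "drop")
  obs$p <- model$p$p[match(obs$barcode, model$p$barcode)]
  obs$score <- obs$reads / obs$p
  obs <- obs[order(-obs$score, obs$barcode), ]
  n_excl <- floor(fraction * nrow(obs))
  model$excluded <- obs$barcode[seq_len(n_excl)]
  model
}

#' Expected number of barcode collisions
#'
#' Under multinomial sampling of N tumors over the barcode space, the mean
#' number of collisions on a barcode with probability p (extra tumors beyond
#' the first sharing that barcode) is `C(p, N) = N p + (1 - p)^N - 1`.
#'
#' @param p Barcode probability (vectorized).
#' @param N Total number of tumors (real-valued allowed, for the solver).
#' @return Expected collisions, clipped at 0 from below.
#' @export
expected_collisions <- function(p, N) {
  stopifnot(all(p >= 0 & p <= 1), all(N >= 0))
  pmax(0, N * p + (1 - p)^N - 1)
}

#' Solve for the true tumor number from the observed distinct count
#'
#' Inverts `N_obs = N - sum_i C_i(p_i, N)` over the retained barcodes
#' (equivalently `N_obs = B - sum_i (1 - p_i)^N`, the expected number of
#' distinct barcodes) for N with Brent's method, then evaluates the expected
#' collisions per barcode at the solution.
#'
#' @param n_obs Observed number of distinct tumors (barcodes).
#' @param model A `barcode_freq_model` (after any exclusion).
#' @param tol Absolute tolerance on the root (default 1e-6).
#' @return Object of class `collision_estimate`: list with `N` (solved total),
#'   `n_obs`, `total_collisions`, and `collisions` (tibble barcode, p, C).
#' @export
solve_total_tumors <- function(n_obs, model, tol = 1e-6) {
  stopifnot(n_obs >= 0)
  p <- retained_p(model)
  B <- length(p)
  if (n_obs >= B) {
    stop("observed distinct tumors (", n_obs,
         ") is not below the retained barcode space (", B, ")", call. = FALSE)
  }
  if (n_obs == 0) {
    N <- 0
  } else {
    objective <- function(N) (B - sum((1 - p)^N)) - n_obs
    upper <- 100 * max(n_obs, 1)
    while (objective(upper) < 0) upper <- upper * 2
    N <- stats::uniroot(objective, lower = n_obs, upper = upper,
                        tol = tol)$root
  }
  C <- expected_collisions(p, N)
  structure(
    list(
      N = N, n_obs = n_obs, total_collisions = sum(C),
      collisions = tibble::tibble(barcode = names(p), p = unname(p),
                                  C = unname(C))
    ),
    class = "collision_estimate"
  )
}

#' @export
print.collision_estimate <- function(x, ...) {
  cat("<collision_estimate> N =", format(x$N), "from n_obs =", x$n_obs,
      "| expected collisions:", format(x$total_collisions), "\n")
  invisible(x)
}

#' Divide tumor sizes by their expected collision load
#'
#' Each call's size (cells, or reads in pancreas mode) is divided by
#' `1 + C_i` of its barcode so that collided barcodes do not overstate tumor
#' size in expectation. Calls on excluded barcodes are dropped with a
#' warning.
#'
#' @param calls Call tibble with `barcode` and `cells` (and/or `reads`).
#' @param estimate A `collision_estimate` from [solve_total_tumors()].
#' @return `calls` with `collision_C` added and sizes divided by
#'   `1 + collision_C`.
#' @export
correct_collisions <- function(calls, estimate) {
  idx <- match(calls$barcode, estimate$collisions$barcode)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " call(s) on excluded barcodes dropped",
            call. = FALSE)
    calls <- calls[!is.na(idx), ]
    idx <- idx[!is.na(idx)]
  }
  calls$collision_C <- estimate$collisions$C[idx]
  if (!is.null(calls[["cells"]])) calls$cells <- calls$cells / (1 + calls$collision_C)
  if (is.null(calls[["cells"]]) && !is.null(calls[["reads"]])) {
    calls$reads <- calls$reads / (1 + calls$collision_C)
  }
  calls
}

#' Collision-correct called tumors per sample and variant
#'
#' Tumors of different variants cannot collide (the variant-barcode pair is
#' the clone identifier), and the multinomial barcode draw happens
#' independently in each mouse, so the solve is applied per (sample,
#' variant): N_obs is that group's number of distinct called barcodes.
#'
#' @param calls Call tibble (`sample`, `variant`, `barcode`, sizes).
#' @param model A `barcode_freq_model` (after exclusion).
#' @return List with `calls` (corrected; `collision_C` column added) and
#'   `estimates` (tibble sample, variant, n_obs, N, expected_collisions).
#' @export
correct_collisions_by_sample <- function(calls, model) {
  if (!is.null(calls[["is_spikein"]])) {
    sp <- calls[calls$is_spikein, ]
    calls <- calls[!calls$is_spikein, ]
  } else sp <- calls[0, ]
  p <- retained_p(model)
  retained <- names(p)

  drop <- !(calls$barcode %in% retained)
  if (any(drop)) {
    warning(sum(drop), " call(s) on excluded barcodes dropped from ",
            "collision correction", call. = FALSE)
    calls <- calls[!drop, ]
  }

  groups <- split(calls, list(calls$sample, calls$variant), drop = TRUE)
  est <- list()
  out <- lapply(groups, function(g) {
    e <- solve_total_tumors(nrow(g), model)
    est[[length(est) + 1L]] <<- tibble::tibble(
      sample = g$sample[1], variant = g$variant[1],
      n_obs = e$n_obs, N = e$N, expected_collisions = e$total_collisions
    )
    correct_collisions(g, e)
  })
  list(calls = dplyr::bind_rows(c(out, list(sp))),
       estimates = dplyr::bind_rows(est))
}
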