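#' Match tumor clones across samples via shared variant-barcode pairs
#'
#' Calls from different samples that carry the identical (variant, barcode)
#' pair are regions of the same clone: groups spanning two or more primary
#' samples are typed region-continuity, and groups containing a metastasis
#' are typed metastatic with the primary member(s) as source candidates.
#' Matching is exact — upstream denoising has already collapsed sequencing
#' errors — and a met-only group (no primary member) is flagged rather than
#' resolved.
#'
#' When a `barcode_freq_model` is supplied, each edge is annotated with a
#' collision hazard: the probability that the pair recurs in the second
#' sample by independent initiation rather than clonality,
#' `1 - (1 - p_i)^{n_partner}` with `n_partner` the partner sample's tumor
#' count.
#'
#' @param calls Tibble with `sample`, `role` ("primary" or "metastasis"),
#'   `variant`, `barcode` and a size column (`cells` or `reads`).
#' @param model Optional `barcode_freq_model` for the collision hazard.
#' @return Object of class `clone_map`: list with `nodes` (calls plus
#'   `clone_id`, `relative_size`, `diameter`) and `edges` (tibble `clone_id`,
#'   `variant`, `barcode`, `sample_a`, `sample_b`, `type`,
#'   `collision_hazard`, `met_only_flag`).
#' @export
match_clones <- function(calls, model = NULL) {
  stopifnot(all(c("sample", "role", "variant", "barcode") %in% names(calls)))
  if (anyDuplicated(calls[, c("sample", "variant", "barcode")])) {
    stop("duplicate (sample, variant, barcode) rows", call. = FALSE)
  }
  nodes <- scale_clone_sizes(calls)
  key <- paste(nodes$variant, nodes$barcode, sep = "|")
  nodes$clone_id <- match(key, unique(key))

  n_by_sample <- table(nodes$sample)
  p_lookup <- if (!is.null(model)) {
    stats::setNames(model$p$p, model$p$barcode)
  } else NULL

  edges <- lapply(split(nodes, nodes$clone_id), function(g) {
    if (nrow(g) < 2L) return(NULL)
    pairs <- utils::combn(seq_len(nrow(g)), 2)
    met_only <- all(g$role == "metastasis")
    dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      type <- if (g$role[i1] == "primary" && g$role[i2] == "primary") {
        "region_continuity"
      } else if (g$role[i1] == "metastasis" && g$role[i2] == "metastasis") {
        "met_met"
      } else "metastatic"
      hazard <- if (!is.null(p_lookup)) {
        p_i <- unname(p_lookup[g$barcode[1]])
        n_partner <- as.numeric(n_by_sample[g$sample[i2]])
        1 - (1 - p_i)^n_partner
      } else NA_real_
      tibble::tibble(
        clone_id = g$clone_id[1], variant = g$variant[1],
        barcode = g$barcode[1],
        sample_a = g$sample[i1], sample_b = g$sample[i2],
        type = type, collision_hazard = hazard,
        met_only_flag = met_only
      )
    }))
  })
  structure(list(nodes = nodes, edges = dplyr::bind_rows(edges)),
            class = "clone_map")
}

#' @export
print.clone_map <- function(x, ...) {
  cat("<clone_map> ", nrow(x$nodes), " calls, ",
      length(unique(x$nodes$clone_id)), " clones, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Within-sample relative tumor sizes and dot diameters
#'
#' Sizes are scaled to the largest tumor within each sample (relative size
#' in (0, 1]); the plotting diameter is the square root of the relative
#' size, so dot area is proportional to size. Without a spike-in there is no
#' absolute scale, so sizes are only comparable within a sample.
#'
#' @param calls Tibble with `sample` and `cells` (preferred) or `reads`.
#' @return `calls` with `relative_size` and `diameter` columns.
#' @export
scale_clone_sizes <- function(calls) {
  size <- if (!is.null(calls[["cells"]]) && !all(is.na(calls[["cells"]]))) {
    calls[["cells"]]
  } else calls[["reads"]]
  stopifnot(all(size > 0))
  max_by_sample <- tapply(size, calls$sample, max)
  calls$relative_size <- size / as.numeric(max_by_sample[calls$sample])
  calls$diameter <- sqrt(calls$relative_size)
  calls
}

#' Export clone-map edges as a DOT graph
#'
#' @param map A `clone_map`.
#' @param path Output path for the Graphviz DOT file.
#' @return `path`, invisibly.
#' @export
write_clone_dot <- function(map, path) {
  esc <- function(x) gsub('"', "", x)
  lines <- c(
    "graph clones {",
    sprintf('  "%s" [label="%s"];', esc(unique(map$nodes$sample)),
            esc(unique(map$nodes$sample))),
    if (nrow(map$edges) > 0) {
      sprintf('  "%s" -- "%s" [label="%s %s" style=%s];',
              esc(map$edges$sample_a), esc(map$edges$sample_b),
              esc(map$edges$variant), esc(map$edges$barcode),
              ifelse(map$edges$type == "metastatic", "dashed", "solid"))
    },
    "}"
  )
  readr::write_lines(lines, path)
  invisible(path)
}
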