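#' Enumerate all rater sets of a given size
#'
#' Lists every subset of `N_R` raters out of `R`, in lexicographic order of
#' the sorted member indices. This ordered list is the backbone of the
#' rater-set assignment design: evaluation targets are dealt to the sets by
#' cycling through this list.
#'
#' @param R Total number of raters.
#' @param N_R Number of raters per evaluation target, `2 <= N_R <= R`.
#'
#' @return A list of `choose(R, N_R)` integer vectors.
#' @examples
#' enumerate_rater_sets(4, 2)
#' @export
enumerate_rater_sets <- function(R, N_R) {
  check_design_args(R, N_R)
  unname(as.list(as.data.frame(combn(R, N_R))))
}

check_design_args <- function(R, N_R) {
  if (N_R < 2 || N_R > R) {
    abort(sprintf("Need 2 <= N_R <= R; got N_R = %d, R = %d.", N_R, R),
          class = "facetlink_invalid_design")
  }
  invisible(NULL)
}

#' Build a rater-set assignment design
#'
#' Allocates exactly `N_R` distinct raters to each of the `J * I`
#' examinee-task evaluation targets: targets are enumerated examinee-major
#' (all tasks of examinee 1, then examinee 2, ...) and target number `t`
#' (0-based) receives the rater set at position `t mod choose(R, N_R)` of
#' [enumerate_rater_sets()]. Cycling balances rater loads and, whenever
#' `J * I >= choose(R, N_R)`, links every rater to every other through shared
#' targets, which is the connectivity linking requires.
#'
#' @param J,I Numbers of examinees and tasks.
#' @inheritParams enumerate_rater_sets
#'
#' @return A `rater_design`: a tibble with columns `examinee`, `task`,
#'   `rater` (one row per assigned rating) and attributes `J`, `I`, `R`,
#'   `N_R`. Deterministic in its arguments.
#' @examples
#' d <- build_design(J = 4, I = 3, R = 4, N_R = 2)
#' connectivity_check(d)$connected
#' @export
build_design <- function(J, I, R, N_R) {
  sets <- enumerate_rater_sets(R, N_R)
  n_sets <- length(sets)
  if (J * I < n_sets) {
    warn(sprintf(
      "Only %d targets for %d rater sets; design may be disconnected (see connectivity_check()).",
      J * I, n_sets))
  }
  targets <- tidyr::expand_grid(examinee = seq_len(J), task = seq_len(I))
  set_idx <- ((seq_len(nrow(targets)) - 1L) %% n_sets) + 1L
  out <- tibble::tibble(
    examinee = rep(targets$examinee, each = N_R),
    task = rep(targets$task, each = N_R),
    rater = unlist(sets[set_idx], use.names = FALSE)
  )
  structure(out, J = J, I = I, R = R, N_R = N_R,
            class = c("rater_design", class(out)))
}

#' Missing-data rate implied by a rater-set design
#'
#' Under a design that assigns `N_R` of `R` raters to every target, the
#' fraction of the fully crossed rating array left unobserved is
#' `(1 - N_R / R) * 100` percent.
#'
#' @inheritParams enumerate_rater_sets
#' @return The missing-data percentage.
#' @examples
#' missing_rate(10, 2) # 80
#' @export
missing_rate <- function(R, N_R) {
  check_design_args(R, N_R)
  (1 - N_R / R) * 100
}

#' Check rater connectivity of an assignment design
#'
#' Linking (and joint estimation generally) requires that all raters be tied
#' together through shared evaluation targets. This builds the graph whose
#' nodes are raters, with an edge between two raters whenever they co-rate a
#' target, and checks that a single connected component covers all `R`
#' raters; raters with no targets at all count as disconnected.
#'
#' @param design A [build_design()] result, or any tibble of
#'   `examinee`, `task`, `rater` triples with an `R` attribute (pass `R`
#'   explicitly otherwise).
#' @param R Total number of raters; defaults to the design's attribute.
#'
#' @return A list with elements `connected` (logical), `n_components`
#'   (components among raters that appear), and `unused_raters` (integer
#'   vector of raters with no assigned target).
#' @export
connectivity_check <- function(design, R = attr(design, "R")) {
  if (is.null(R)) abort("Supply R (not recorded on the design).",
                        class = "facetlink_invalid_design")
  pairs <- design |>
    dplyr::summarise(raters = list(sort(unique(.data$rater))),
                     .by = c("examinee", "task")) |>
    dplyr::pull("raters")
  edges <- purrr::map(pairs, function(rs) {
    if (length(rs) < 2) return(NULL)
    t(combn(rs, 2))
  })
  edges <- do.call(rbind, edges)
  used <- sort(unique(design$rater))
  g <- igraph::make_empty_graph(n = R, directed = FALSE)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)
  n_comp_used <- length(unique(comp$membership[used]))
  unused <- setdiff(seq_len(R), used)
  list(
    connected = length(unused) == 0L && n_comp_used == 1L,
    n_components = n_comp_used,
    unused_raters = unused
  )
}
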