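#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PMF grid
#'
#' Drops the class and attribute baggage and returns the plain per-bin
#' tibble (bin bounds, occupancy, free energy, empty flag).
#'
#' @param x a `pmf_grid`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.pmf_grid <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pmf_grid")
  for (a in c("axes", "temperature", "reference", "bulk_density",
              "empty_bin_value", "kB"))
    attr(out, a) <- NULL
  tibble::as_tibble(out)
}

#' @rdname tidy.pmf_grid
#' @export
glance.pmf_grid <- function(x, ...) {
  tibble(
    axes = paste(attr(x, "axes"), collapse = ","),
    n_bins = nrow(x),
    n_empty = sum(x$empty),
    temperature = attr(x, "temperature"),
    reference = attr(x, "reference"),
    bulk_density = attr(x, "bulk_density"),
    empty_bin_value = attr(x, "empty_bin_value"),
    min_free_energy = min(x$free_energy),
    max_free_energy = max(x$free_energy))
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat("<pmf_grid> ", paste(attr(x, "axes"), collapse = " x "), ", ",
      nrow(x), " bins (", sum(x$empty), " empty), T = ",
      attr(x, "temperature"), " K, ", attr(x, "reference"), "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy / glance methods for TMD schedules
#'
#' `tidy()` evaluates the target-RMSD schedule on a time grid; `glance()`
#' returns the one-row summary (drift rate, force constant, biased atoms).
#'
#' @param x a [tmd_schedule()].
#' @param n number of time points for `tidy()`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.tmd_schedule <- function(x, n = 101L, ...) {
  t <- seq(0, x$duration_ns, length.out = n)
  tibble(time_ns = t, target_rmsd = x$rho(t))
}

#' @rdname tidy.tmd_schedule
#' @export
glance.tmd_schedule <- function(x, ...) {
  tibble(initial_rmsd = x$initial_rmsd, duration_ns = x$duration_ns,
         drift_rate = x$drift_rate, k = x$k, n_atoms = x$n_atoms)
}
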