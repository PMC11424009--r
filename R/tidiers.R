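#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a redundancy solution
#'
#' @param x A `gaitmet_solution`.
#' @param ... Unused.
#' @return The per-muscle state tibble (one row per muscle and mesh node).
#' @method tidy gaitmet_solution
#' @export
tidy.gaitmet_solution <- function(x, ...) x$states

#' One-row summary of a redundancy solution
#'
#' @param x A `gaitmet_solution`.
#' @param ... Unused.
#' @method glance gaitmet_solution
#' @export
glance.gaitmet_solution <- function(x, ...) {
  tibble::tibble(
    workflow = x$workflow,
    n_mesh = x$n_mesh,
    converged = x$status$converged,
    iterations = x$status$iterations,
    objective = x$status$deviance,
    effort = x$objective$effort,
    reserve = x$objective$reserve,
    max_reserve_share = max(x$reserve_report$reserve_share),
    speed = x$trial_info$speed,
    cycle_duration = x$trial_info$cycle_duration
  )
}

#' @method tidy gaitmet_rmcorr
#' @export
tidy.gaitmet_rmcorr <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance gaitmet_rmcorr
#' @export
glance.gaitmet_rmcorr <- function(x, ...) tidy(x)

#' Tidy the suprathreshold clusters of a 1-D permutation test
#'
#' @param x A `gaitmet_snpm`.
#' @param ... Unused.
#' @method tidy gaitmet_snpm
#' @export
tidy.gaitmet_snpm <- function(x, ...) x$clusters

#' @method glance gaitmet_snpm
#' @export
glance.gaitmet_snpm <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, alpha = x$alpha,
    n_clusters = nrow(x$clusters), n_perm = x$n_perm_used,
    max_t = max(abs(x$t))
  )
}

#' @export
print.gaitmet_solution <- function(x, ...) {
  cat(sprintf(
    "<gaitmet_solution> workflow %s | %d muscles x %d nodes | objective %.4g | %s\n",
    x$workflow, length(unique(x$states$muscle)), x$n_mesh,
    x$status$deviance,
    if (x$status$converged) "converged" else paste("info", x$status$info)
  ))
  invisible(x)
}

#' @export
print.gaitmet_snpm <- function(x, ...) {
  cat(sprintf("<gaitmet_snpm> threshold %.3f (alpha %.2f, %d permutations), %d cluster(s)\n",
              x$threshold, x$alpha, x$n_perm_used, nrow(x$clusters)))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}
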