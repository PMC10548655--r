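## Golden-section maximization of AG over a one-dimensional assembler
## parameter, with a fixed evaluation budget. The search runs on the unit
## interval and maps through the space's transform, so a log10 space gives
## coarse tuning at high divergences and fine tuning at low ones.

#' Define a one-dimensional search space
#'
#' @param lower,upper Parameter bounds, `lower < upper`.
#' @param transform `"identity"` for a linear scale or `"log10"` to search
#'   the exponent (requires `lower > 0`).
#' @return An object of class `search_space`.
#' @export
search_space <- function(lower, upper, transform = c("identity", "log10")) {
  transform <- match.arg(transform)
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    agm_stop("search space requires numeric lower < upper",
             "agm_invalid_argument")
  }
  if (transform == "log10" && lower <= 0) {
    agm_stop("log10 search space requires lower > 0", "agm_invalid_argument")
  }
  structure(list(lower = lower, upper = upper, transform = transform),
            class = "search_space")
}

#' Map a unit-interval coordinate to a parameter value
#'
#' @param u Coordinate(s) in `[0, 1]`.
#' @param space A [search_space()].
#' @return Parameter value(s) in `[lower, upper]`.
#' @export
to_parameter <- function(u, space) {
  if (any(is.na(u)) || any(u < 0) || any(u > 1)) {
    agm_stop("u must lie in [0, 1]", "agm_invalid_argument")
  }
  if (space$transform == "identity") {
    space$lower + u * (space$upper - space$lower)
  } else {
    la <- log10(space$lower)
    lb <- log10(space$upper)
    10^(la + u * (lb - la))
  }
}

#' Golden-section maximization under a fixed budget
#'
#' Maximizes `objective(parameter)` with exactly `budget` objective calls.
#' The first two evaluations are the interior points of the unit interval,
#' `u = (sqrt(5)-1)/(sqrt(5)+1) = 0.3819660...` and its complement
#' `0.6180340...`; each subsequent step discards the outer sub-interval on
#' the side of the worse interior point and evaluates one new interior
#' point, reusing the surviving one. When the two interior values tie the
#' right sub-interval is dropped, biasing toward smaller parameters.
#' Evaluations are memoized on the parameter rounded to 10 significant
#' digits, so a re-proposed point is never re-run. The result is the best
#' over all evaluated points (not the final bracket midpoint), ties broken
#' toward the smaller parameter.
#'
#' @param objective Function of one parameter value returning either a
#'   number or a list with elements `ag` (number) and optionally
#'   `artifact`.
#' @param space A [search_space()].
#' @param budget Number of objective evaluations, at least 2; default 10.
#' @return An object of class `search_trace`: `evaluations` (data frame of
#'   index, u, parameter, ag), `artifacts` (list), `best_parameter`,
#'   `best_ag`, `bracket` (final `[a, b]` in u-coordinates).
#' @export
golden_section_maximize <- function(objective, space, budget = 10L) {
  if (!is_count(budget) || budget < 2) {
    agm_stop("budget must be an integer >= 2", "agm_invalid_argument")
  }
  r <- (sqrt(5) - 1) / 2
  memo <- new.env(parent = emptyenv())
  evals <- list()
  artifacts <- list()
  n_calls <- 0L
  eval_u <- function(u) {
    p <- to_parameter(u, space)
    key <- sprintf("%.10e", signif(p, 10L))
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- tryCatch(objective(p), error = function(e) {
      agm_stop(sprintf(
        "objective failed at parameter %s (evaluation %d): %s",
        fmt_num(p), n_calls + 1L, conditionMessage(e)), "agm_backend_error")
    })
    ag <- if (is.list(res)) res$ag else res
    artifact <- if (is.list(res)) res$artifact else NULL
    n_calls <<- n_calls + 1L
    evals[[n_calls]] <<- data.frame(index = n_calls, u = u, parameter = p,
                                    ag = as.numeric(ag))
    artifacts[[n_calls]] <<- artifact
    memo[[key]] <- as.numeric(ag)
    memo[[key]]
  }
  a <- 0
  b <- 1
  x1 <- a + (1 - r) * (b - a)
  x2 <- a + r * (b - a)
  f1 <- eval_u(x1)
  f2 <- eval_u(x2)
  guard <- 0L
  while (n_calls < budget && guard < 1000L) {
    guard <- guard + 1L
    if (f1 >= f2) {  # drop the right sub-interval (ties included)
      b <- x2
      x2 <- x1
      f2 <- f1
      x1 <- a + (1 - r) * (b - a)
      f1 <- eval_u(x1)
    } else {
      a <- x1
      x1 <- x2
      f1 <- f2
      x2 <- a + r * (b - a)
      f2 <- eval_u(x2)
    }
  }
  tab <- do.call(rbind, evals)
  best_ag <- max(tab$ag)
  cand <- tab[tab$ag == best_ag, , drop = FALSE]
  best_parameter <- min(cand$parameter)
  structure(list(evaluations = tab, artifacts = artifacts,
                 best_parameter = best_parameter, best_ag = best_ag,
                 bracket = c(a, b)), class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("<search_trace: %d evaluations, best AG %s at parameter %s>\n",
              nrow(x$evaluations), fmt_num(x$best_ag),
              fmt_num(x$best_parameter)))
  invisible(x)
}

#' Optimize an assembler parameter for AG, then assemble finally
#'
#' Runs [golden_section_maximize()] with the backend's objective (assemble
#' at a parameter value, compute AG on the result), then invokes the
#' backend once more at the best parameter in final mode (all reads, no
#' gene-only restriction) and returns that assembly alongside the trace.
#'
#' @param backend A backend object (see [mock_backend()]) with fields
#'   `space`, `objective(parameter)` and `assemble_final(parameter)`.
#' @param budget Number of objective evaluations; default 10.
#' @return List of class `ag_optimization` with `trace` (a `search_trace`)
#'   and `final_assembly`.
#' @export
optimize_assembly <- function(backend, budget = 10L) {
  trace <- golden_section_maximize(backend$objective, backend$space, budget)
  final <- backend$assemble_final(trace$best_parameter)
  structure(list(trace = trace, final_assembly = final,
                 backend = backend$name), class = "ag_optimization")
}

#' Write a search trace as TSV
#'
#' @param trace A `search_trace` from [golden_section_maximize()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace$evaluations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
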