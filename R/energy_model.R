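#' Nearest-neighbor RNA energy model
#'
#' Loads the packaged thermodynamic tables: Watson-Crick + GU stacking
#' energies, size-dependent hairpin/bulge/internal loop initiation penalties
#' with Jacobson-Stockmayer log extrapolation beyond the tabulated sizes, and
#' an affine multiloop cost. All values are in kcal/mol at 37 degrees C.
#' Internally the model stores integer centi-kcal so that folded and
#' re-evaluated energies compare exactly.
#'
#' The model is a stand-in for a full Mfold-style energy function: no dangles,
#' no coaxial stacking, no pseudoknots, minimum hairpin loop of
#' `min_hairpin` unpaired bases, and interior loops capped at `max_interior`
#' total unpaired bases. The analyses downstream depend on the relative
#' ordering of domain free energies, not on any one program's exact values.
#'
#' @param stack_file,loop_file,multiloop_file Optional paths to replacement
#'   TSV tables in the packaged format (see `inst/extdata/`).
#' @param min_hairpin Minimum number of unpaired bases in a hairpin loop.
#' @param max_interior Maximum total unpaired bases in a bulge/interior loop
#'   considered during folding (evaluation of given structures is uncapped).
#' @return An object of class `energy_model`.
#' @examples
#' m <- energy_model()
#' m$multiloop
#' @export
energy_model <- function(stack_file = NULL, loop_file = NULL,
                         multiloop_file = NULL, min_hairpin = 3L,
                         max_interior = 30L) {
  stack_file <- stack_file %||%
    system.file("extdata", "stack_energies.tsv", package = "mirhairpin")
  loop_file <- loop_file %||%
    system.file("extdata", "loop_penalties.tsv", package = "mirhairpin")
  multiloop_file <- multiloop_file %||%
    system.file("extdata", "multiloop_params.tsv", package = "mirhairpin")

  stk <- readr::read_tsv(stack_file, col_types = "ccd", progress = FALSE)
  loops <- readr::read_tsv(loop_file, col_types = "cid", progress = FALSE)
  ml <- readr::read_tsv(multiloop_file, col_types = "cd", progress = FALSE)

  pair_levels <- c("AU", "CG", "GC", "GU", "UA", "UG")
  stack <- matrix(NA_integer_, 6, 6, dimnames = list(pair_levels, pair_levels))
  stack[cbind(match(stk$outer, pair_levels), match(stk$inner, pair_levels))] <-
    as.integer(round(100 * stk$dg))
  if (anyNA(stack)) stop("stacking table is incomplete")
  # strand-flip symmetry is assumed by the folder
  flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (o in pair_levels) for (i in pair_levels) {
    if (stack[o, i] != stack[flip(i), flip(o)]) {
      stop("stacking table is not symmetric under strand flip: ", o, "/", i)
    }
  }

  centi <- function(type) {
    d <- loops[loops$loop_type == type, ]
    d <- d[order(d$size), ]
    list(size = d$size, e = as.integer(round(100 * d$dg)))
  }
  mlv <- stats::setNames(as.integer(round(100 * ml$dg)), ml$param)
  for (p in c("offset", "branch", "unpaired")) {
    if (!p %in% names(mlv)) stop("multiloop table lacks parameter: ", p)
  }

  structure(
    list(
      pair_levels = pair_levels,
      stack = stack,
      hairpin = centi("hairpin"),
      bulge = centi("bulge"),
      internal = centi("internal"),
      multiloop = c(offset = mlv[["offset"]], branch = mlv[["branch"]],
                    unpaired = mlv[["unpaired"]]),
      min_hairpin = as.integer(min_hairpin),
      max_interior = as.integer(max_interior)
    ),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> nearest-neighbor RNA model\n")
  cat("  pairs:", paste(x$pair_levels, collapse = " "), "\n")
  cat("  min hairpin loop:", x$min_hairpin,
      " max interior loop:", x$max_interior, "\n")
  cat("  multiloop (kcal/mol): offset", x$multiloop[["offset"]] / 100,
      "branch", x$multiloop[["branch"]] / 100,
      "unpaired", x$multiloop[["unpaired"]] / 100, "\n")
  invisible(x)
}

# integer centi-kcal penalty for loop sizes, extrapolating beyond the table
# with the same 1.08*ln(n/n_ref) law used to build it
loop_penalty_centi <- function(model, type, sizes) {
  tab <- model[[type]]
  maxs <- max(tab$size)
  out <- integer(length(sizes))
  small <- sizes <= maxs
  idx <- match(sizes[small], tab$size)
  if (anyNA(idx)) stop("no ", type, " penalty for size ",
                       paste(sizes[small][is.na(idx)], collapse = ", "))
  out[small] <- tab$e[idx]
  if (any(!small)) {
    base <- tab$e[match(maxs, tab$size)]
    out[!small] <- as.integer(round(base + 108 * log(sizes[!small] / maxs)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
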