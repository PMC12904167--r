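#' @keywords internal
"_PACKAGE"

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so that callers' random streams are not disturbed.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a stream of per-item seeds from a root seed
#'
#' All randomness in a simulation flows from one root seed; per-image or
#' per-fiber seeds are drawn from it so that any single item can be
#' regenerated independently.  Seeds stay below 2^31 - 1.
#'
#' @param root_seed Integer root seed.
#' @param n Number of seeds to draw.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(root_seed, n) {
  with_seed(root_seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# stop() with sprintf-style formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Label 8-connected components of a binary mask
#'
#' Connected-component labelling under 8-connectivity (pixels touching
#' edge- or corner-wise belong to one component), the connectivity the
#' hotspot and skeleton analyses are specified in.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  on <- which(mask != 0)
  lab <- matrix(0L, nr, nc)
  if (length(on) == 0L) return(lab)
  id <- integer(length(mask)); id[on] <- seq_along(on)
  row <- ((on - 1L) %% nr) + 1L
  # candidate neighbour offsets in column-major indexing
  edges <- list()
  add <- function(off, ok) {
    nb <- on[ok] + off
    good <- nb >= 1L & nb <= length(id)
    a <- on[ok][good]; b <- nb[good]
    keep <- id[b] > 0L
    if (any(keep)) edges[[length(edges) + 1L]] <<- cbind(id[a[keep]], id[b[keep]])
  }
  add(1L, row < nr)              # S
  add(nr, rep(TRUE, length(on))) # E
  add(nr + 1L, row < nr)         # SE
  add(nr - 1L, row > 1L)         # NE
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(on) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(on)
  }
  # renumber components in first-appearance order for determinism
  memb <- as.integer(factor(memb, levels = unique(memb)))
  lab[on] <- memb
  lab
}
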