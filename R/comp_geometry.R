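#' Canonical behaviour part names
#'
#' The four parts of a 24-h movement behaviour composition, in canonical
#' order: sleep, sedentary behaviour (SB), light physical activity (LPA),
#' and moderate-to-vigorous physical activity (MVPA).
#'
#' @return Character vector of length 4.
#' @export
behavior_parts <- function() c("sleep", "sb", "lpa", "mvpa")

# Coerce a composition input (vector or matrix/data.frame with one row per
# composition) to a numeric matrix with part columns.
as_comp_matrix <- function(x, parts = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  storage.mode(x) <- "double"
  if (is.null(parts)) {
    parts <- colnames(x)
    if (is.null(parts)) {
      parts <- if (ncol(x) == 4L) behavior_parts() else paste0("part", seq_len(ncol(x)))
    }
  } else {
    if (!is.null(colnames(x)) && all(parts %in% colnames(x))) x <- x[, parts, drop = FALSE]
  }
  if (length(parts) != ncol(x)) stop("composition has ", ncol(x), " parts; expected ", length(parts))
  colnames(x) <- parts
  x
}

#' Close a composition to a fixed total
#'
#' Rescales strictly positive parts so they sum to `total` (24 h by default).
#' Closure only changes the scale of a composition, never the relative
#' information it carries.
#'
#' @param parts Numeric vector of parts, or a matrix/data.frame with one
#'   composition per row.
#' @param total Closure constant, in the same units as `parts` (default 24).
#' @return Closed composition(s), same shape as the input (vectors stay
#'   vectors), summing to `total` per composition.
#' @examples
#' close_comp(c(sleep = 1, sb = 1, lpa = 1, mvpa = 1))
#' @export
close_comp <- function(parts, total = 24) {
  vec <- is.null(dim(parts))
  m <- as_comp_matrix(parts)
  check_positive_parts(m)
  if (!is.numeric(total) || length(total) != 1L || !is.finite(total) || total <= 0)
    stop("'total' must be a single positive number")
  out <- m * (total / rowSums(m))
  if (vec) out[1L, ] else out
}

check_positive_parts <- function(m) {
  bad <- which(!(is.finite(m) & m > 0), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    part <- colnames(m)[bad[1L, "col"]]
    stop("composition part '", part, "' is zero, negative or non-finite ",
         "(row ", bad[1L, "row"], "); compositions must be strictly positive")
  }
  invisible(m)
}

#' Default sequential binary partition for the 4 behaviours
#'
#' The default SBP splits (sleep | SB, LPA, MVPA), then (SB | LPA, MVPA),
#' then (LPA | MVPA). Every reported quantity downstream (block F-tests,
#' predictions, Goldilocks compositions) is invariant to this choice; it
#' only affects the interpretation of individual ilr coefficients.
#'
#' @return A list of 3 partitions, each with elements `up` and `down`
#'   (character vectors of part names).
#' @export
default_sbp <- function() {
  list(
    list(up = "sleep", down = c("sb", "lpa", "mvpa")),
    list(up = "sb",    down = c("lpa", "mvpa")),
    list(up = "lpa",   down = "mvpa")
  )
}

validate_sbp <- function(sbp, parts) {
  if (!is.list(sbp) || length(sbp) != length(parts) - 1L)
    stop("SBP must be a list of ", length(parts) - 1L, " binary partitions")
  # active groups: starts as the full part set; each split consumes one group
  active <- list(sort(parts))
  key <- function(g) paste(sort(g), collapse = "|")
  for (i in seq_along(sbp)) {
    p <- sbp[[i]]
    if (!is.list(p) || !all(c("up", "down") %in% names(p)))
      stop("SBP step ", i, " must have 'up' and 'down' groups")
    up <- p$up; down <- p$down
    if (length(up) == 0L || length(down) == 0L)
      stop("SBP step ", i, ": both groups must be non-empty")
    if (length(intersect(up, down)) > 0L)
      stop("SBP step ", i, ": groups overlap (", paste(intersect(up, down), collapse = ", "), ")")
    whole <- sort(c(up, down))
    if (anyDuplicated(whole)) stop("SBP step ", i, ": duplicated part")
    if (!all(whole %in% parts)) stop("SBP step ", i, ": unknown part(s) ",
                                     paste(setdiff(whole, parts), collapse = ", "))
    hit <- vapply(active, function(g) identical(key(g), key(whole)), logical(1))
    if (!any(hit))
      stop("SBP step ", i, ": group {", paste(whole, collapse = ", "),
           "} is not a group produced by the preceding splits (non-sequential ",
           "or non-exhaustive partition)")
    active <- active[!hit]
    if (length(up) > 1L) active <- c(active, list(sort(up)))
    if (length(down) > 1L) active <- c(active, list(sort(down)))
  }
  invisible(sbp)
}

#' Build an orthonormal ilr contrast basis from a sequential binary partition
#'
#' Each SBP step contributes one balance column: parts in the `up` group get
#' coefficient \eqn{+\sqrt{s/(r(r+s))}} and parts in the `down` group
#' \eqn{-\sqrt{r/(s(r+s))}}, where r and s are the group sizes. The
#' resulting 4x3 matrix V satisfies V'V = I and has zero column sums, so
#' ilr coordinates are invariant to closure.
#'
#' @param sbp A sequential binary partition as returned by [default_sbp()].
#' @param parts Part names (default the 4 behaviours).
#' @return An object of class `contrast_basis` with elements `sbp`, `parts`
#'   and `matrix` (the 4x3 contrast matrix).
#' @examples
#' b <- make_contrast_basis()
#' crossprod(b$matrix)  # identity
#' @export
make_contrast_basis <- function(sbp = default_sbp(), parts = behavior_parts()) {
  validate_sbp(sbp, parts)
  D <- length(parts)
  V <- matrix(0, nrow = D, ncol = D - 1L, dimnames = list(parts, paste0("z", seq_len(D - 1L))))
  for (i in seq_along(sbp)) {
    r <- length(sbp[[i]]$up); s <- length(sbp[[i]]$down)
    V[sbp[[i]]$up, i]   <-  sqrt(s / (r * (r + s)))
    V[sbp[[i]]$down, i] <- -sqrt(r / (s * (r + s)))
  }
  structure(list(sbp = sbp, parts = parts, matrix = V), class = "contrast_basis")
}

#' @export
print.contrast_basis <- function(x, ...) {
  cat("ilr contrast basis (", length(x$parts), " parts, ",
      ncol(x$matrix), " balances)\n", sep = "")
  for (i in seq_along(x$sbp)) {
    cat(sprintf("  z%d: (%s | %s)\n", i,
                paste(x$sbp[[i]]$up, collapse = ","),
                paste(x$sbp[[i]]$down, collapse = ",")))
  }
  invisible(x)
}

#' Isometric log-ratio coordinates of compositions
#'
#' Maps strictly positive compositions to unconstrained real coordinates,
#' `z = V' log(x)`. Because the basis columns sum to zero the result does
#' not depend on whether the input is closed.
#'
#' @param comp Composition vector, or matrix with one composition per row.
#' @param basis A `contrast_basis` (default SBP if omitted).
#' @return Numeric vector (for a single composition) or matrix of ilr
#'   coordinates `z1..z3`.
#' @examples
#' ilr_coords(c(sleep = 6, sb = 6, lpa = 6, mvpa = 6))  # the origin
#' @export
ilr_coords <- function(comp, basis = make_contrast_basis()) {
  vec <- is.null(dim(comp))
  m <- as_comp_matrix(comp, basis$parts)
  check_positive_parts(m)
  z <- log(m) %*% basis$matrix
  if (vec) z[1L, ] else z
}

#' Inverse ilr transform
#'
#' Maps ilr coordinates back to closed compositions:
#' `close(exp(V z), total)`.
#'
#' @param z ilr coordinate vector, or matrix with one coordinate row per
#'   composition.
#' @param basis A `contrast_basis`.
#' @param total Closure constant (default 24 h).
#' @return Closed composition(s).
#' @export
ilr_inverse <- function(z, basis = make_contrast_basis(), total = 24) {
  vec <- is.null(dim(z))
  if (vec) z <- matrix(z, nrow = 1L)
  if (!all(is.finite(z))) stop("ilr coordinates must be finite")
  if (ncol(z) != ncol(basis$matrix))
    stop("expected ", ncol(basis$matrix), " ilr coordinates, got ", ncol(z))
  # subtract the rowwise max before exponentiating so large |z| cannot overflow
  lx <- z %*% t(basis$matrix)
  lx <- lx - apply(lx, 1L, max)
  out <- close_comp(exp(lx), total = total)
  colnames(out) <- basis$parts
  if (vec) out[1L, ] else out
}

#' Compositional mean (Aitchison centre)
#'
#' Part-wise geometric means, closed to the total. Identical (up to
#' numerical error) to taking the arithmetic mean in ilr coordinates and
#' mapping back, for any contrast basis.
#'
#' @param comps Matrix/data.frame of compositions, one per row (a single
#'   vector is treated as one composition).
#' @param total Closure constant (default 24 h).
#' @return A single closed composition (named numeric vector).
#' @examples
#' comp_mean(rbind(c(12, 6, 3, 3), c(6, 12, 3, 3)))
#' @export
comp_mean <- function(comps, total = 24) {
  m <- as_comp_matrix(comps)
  if (nrow(m) == 0L) stop("cannot take the compositional mean of an empty set")
  check_positive_parts(m)
  g <- exp(colMeans(log(m)))
  close_comp(g, total = total)
}
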