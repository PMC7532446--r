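# Internal helpers shared across modules.

# Run `expr` with a private RNG state seeded by `seed`; if seed is NULL the
# current global RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# sd() that returns 0 for length-1 input instead of NA.
sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

# Coefficient of variation with a 0/0 -> 0 convention.
cv0 <- function(x) {
  m <- mean(x)
  if (length(x) < 2 || m == 0) return(0)
  stats::sd(x) / m
}

# Least-squares slope of y against 1..length(y); 0 when fewer than 2 points.
ls_slope <- function(y) {
  n <- length(y)
  if (n < 2) return(0)
  x <- seq_len(n)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# Node ages (Myr before present) for an ultrametric-ish tree: root age minus
# root-to-node path length, clamped at 0.
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth) - depth
  age[age < 0] <- 0
  age
}

tree_root_age <- function(tree) max(ape::node.depth.edgelength(tree))

assert_ultrametric <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (diff(range(depth)) > tol)
    stop_("tree is not ultrametric within tolerance %g Myr", tol)
  invisible(TRUE)
}
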