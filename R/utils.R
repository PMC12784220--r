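#' @keywords internal
"_PACKAGE"

#' @importFrom stats chisq.test cor integrate kmeans lm lm.fit median
#'   model.matrix oneway.test p.adjust pnorm pt qnorm qt rchisq resid rnorm
#'   runif sd setNames t.test var
#' @importFrom utils combn head packageVersion read.csv read.table write.csv
#'   write.table
NULL

# Deterministic derivation of a bounded child seed from (seed, stage index).
# Keeps every derived seed inside the 32-bit integer range R requires.
child_seed <- function(seed, stage) {
  s0 <- as.numeric(seed) %% 2147483647
  lo <- s0 %% 65536
  hi <- s0 %/% 65536
  as.integer((lo * 32749 + hi * 30011 + as.numeric(stage) * 48271) %% 2147483629 + 1)
}

# Evaluate expr with a temporary RNG state restored afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Wrap angular values (degrees) into (-180, 180].
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Wrap angular values (radians) into (-pi, pi].
wrap_rad <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

log_sum_exp_rows <- function(M) {
  m <- M[, 1]
  G <- ncol(M)
  if (G > 1) for (g in 2:G) m <- pmax(m, M[, g])
  m[!is.finite(m)] <- 0            # all -Inf rows stay -Inf via log(0)
  m + log(rowSums(exp(M - m)))
}

as_matrix_table <- function(x, what = "table") {
  if (is.data.frame(x)) {
    idcol <- which(names(x) %in% c("subject_id", "roi_id"))
    if (length(idcol)) {
      rn <- as.character(x[[idcol[1]]])
      x <- x[, -idcol, drop = FALSE]
      x <- as.matrix(x)
      rownames(x) <- rn
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) stopf("%s must be a numeric matrix", what)
  x
}
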