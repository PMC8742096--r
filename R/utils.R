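## Internal helpers: argument checking and small numerics shared across modules.

stop_craniosh <- function(kind, msg, ...) {
  stop(structure(
    class = c(paste0("craniosh_", kind), "craniosh_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_num_matrix <- function(x, name = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || ncol(x) != 3L)
    stop_craniosh("format", "%s must be an N x 3 numeric matrix", name)
  storage.mode(x) <- "double"
  if (!all(is.finite(x)))
    stop_craniosh("format", "%s contains non-finite coordinates", name)
  dimnames(x) <- NULL
  x
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop_craniosh("geometry", "cannot normalize a zero vector")
  v / n
}

## Area of the triangle spanned by three 3D points (mm^2).
triangle_area <- function(p1, p2, p3) {
  u <- p2 - p1
  v <- p3 - p1
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  0.5 * vnorm(cr)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Wrap an angle in degrees to [0, 360).
wrap360 <- function(x) {
  y <- x %% 360
  y[y == 360] <- 0
  y
}
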