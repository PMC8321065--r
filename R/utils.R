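# Internal helpers: typed conditions, seeded evaluation, interpolation.

# Typed error constructor.  `class` is one of the package condition classes:
# validation, geometry, dimensionality, io, shape, checkpoint, state,
# divergence.  The CLI maps validation-like classes to exit code 2 and
# runtime classes to exit code 3.
ff_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(paste0("ff_", class, "_error"), "ff_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ff_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so seeded internals never perturb user code.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage seed from a run seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647)
}

stopifnot_finite <- function(x, what) {
  nbad <- sum(!is.finite(x))
  if (nbad > 0)
    ff_stop("validation", "%s contains %d non-finite value(s)", what, nbad)
  invisible(x)
}

# Trilinear interpolation of a 3D array onto a new grid size.
# Cell-centre alignment: source coordinate of target index i (1-based) is
# (i - 0.5) * src/dst + 0.5, clamped to [1, src].
trilinear_resize <- function(vol, out_dim) {
  d <- dim(vol)
  if (length(d) != 3L) ff_stop("validation", "trilinear_resize expects a 3D array")
  coords <- lapply(1:3, function(a) {
    if (out_dim[a] == d[a]) return(list(lo = seq_len(d[a]), hi = seq_len(d[a]), w = rep(0, d[a])))
    if (d[a] == 1L) return(list(lo = rep(1L, out_dim[a]), hi = rep(1L, out_dim[a]),
                                w = rep(0, out_dim[a])))
    x <- ((seq_len(out_dim[a]) - 0.5) * d[a] / out_dim[a]) + 0.5
    x <- pmin(pmax(x, 1), d[a])
    lo <- pmin(floor(x), d[a] - 1L)
    list(lo = as.integer(lo), hi = as.integer(lo + 1L), w = x - lo)
  })
  out <- array(0, out_dim)
  # gather the 8 corners with outer-product weights, fully vectorized
  for (ch in 0:7) {
    ih <- if (bitwAnd(ch, 1L)) coords[[1]]$hi else coords[[1]]$lo
    iw <- if (bitwAnd(ch, 2L)) coords[[2]]$hi else coords[[2]]$lo
    id <- if (bitwAnd(ch, 4L)) coords[[3]]$hi else coords[[3]]$lo
    wh <- if (bitwAnd(ch, 1L)) coords[[1]]$w else 1 - coords[[1]]$w
    ww <- if (bitwAnd(ch, 2L)) coords[[2]]$w else 1 - coords[[2]]$w
    wd <- if (bitwAnd(ch, 4L)) coords[[3]]$w else 1 - coords[[3]]$w
    wt <- outer(outer(wh, ww), wd)
    out <- out + vol[ih, iw, id, drop = FALSE] * wt
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
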