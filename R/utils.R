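# internal helpers shared across modules

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
}

is_binary_array <- function(x) {
  is.array(x) && length(dim(x)) == 3L &&
    (is.logical(x) || all(x %in% c(0, 1)))
}

as_mask <- function(x, name = "mask") {
  abort_if(!is.array(x) || length(dim(x)) != 3L,
           sprintf("`%s` must be a 3D array", name))
  if (!is.logical(x)) {
    abort_if(!all(x %in% c(0, 1)), sprintf("`%s` must be binary", name))
    x <- array(x != 0, dim(x))
  }
  x
}

check_same_shape <- function(a, b, names = c("mask_a", "mask_b")) {
  abort_if(!identical(dim(a), dim(b)),
           sprintf("`%s` and `%s` have different shapes (%s vs %s)",
                   names[1], names[2],
                   paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
}

check_spacing <- function(spacing) {
  abort_if(length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0),
           "`spacing_mm` must be three strictly positive values")
  as.numeric(spacing)
}

# Deterministic substream seeds below 2^31, derived from a master seed and a
# stage tag so the stages draw from independent streams.
derive_seed <- function(master, tag, index = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  val <- (as.numeric(master) * 48271 + h * 16807 + as.numeric(index) * 69621)
  as.integer(val %% 2147483629) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# physical voxel-centre coordinate grids for a volume
coord_grid <- function(shape, spacing) {
  list(
    x = array(rep((seq_len(shape[1]) - 1) * spacing[1], times = shape[2] * shape[3]), shape),
    y = array(rep(rep((seq_len(shape[2]) - 1) * spacing[2], each = shape[1]),
                  times = shape[3]), shape),
    z = array(rep((seq_len(shape[3]) - 1) * spacing[3], each = shape[1] * shape[2]), shape)
  )
}
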