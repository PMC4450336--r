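# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic generators in the package route through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Axis-aligned world-coordinate box: list(lo = c(x,y,z), hi = c(x,y,z)) mm.
as_box <- function(box) {
  if (is.null(box)) return(NULL)
  if (!is.list(box) || !all(c("lo", "hi") %in% names(box)))
    stop("a box must be list(lo = c(x,y,z), hi = c(x,y,z)) in mm", call. = FALSE)
  lo <- as.numeric(box$lo); hi <- as.numeric(box$hi)
  if (length(lo) != 3L || length(hi) != 3L || any(!is.finite(c(lo, hi))))
    stop("box corners must be 3 finite numbers each", call. = FALSE)
  list(lo = pmin(lo, hi), hi = pmax(lo, hi))
}

# Logical array marking voxels whose centers fall inside a world box.
box_mask <- function(image, box) {
  box <- as_box(box)
  d <- grid_dim(image)
  ax <- lapply(1:3, function(a) {
    c <- (seq_len(d[a]) - 1) * image$spacing[a] + image$origin[a]
    c >= box$lo[a] & c <= box$hi[a]
  })
  outer(outer(ax[[1]], ax[[2]], "&"), ax[[3]], "&")
}
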