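# Internal helpers shared across modules.

cx_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cortexr_error", "error"),
                      call = call))
}

cx_warn <- function(msg) warning(msg, call. = FALSE)

# shift a 3-D array by integer offset s = c(dx, dy, dz), padding with `fill`
shift3 <- function(a, s, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  dst <- src <- vector("list", 3L)
  for (i in 1:3) {
    lo <- max(1L, 1L + s[i]); hi <- min(d[i], d[i] + s[i])
    if (lo > hi) return(out)
    dst[[i]] <- lo:hi
    src[[i]] <- (lo - s[i]):(hi - s[i])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# neighbor offsets for a digital connectivity
conn_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  city <- rowSums(abs(g))
  cheb <- apply(abs(g), 1L, max)
  keep <- switch(as.character(connectivity),
    "6"  = city == 1,
    "18" = cheb == 1 & city <= 2,
    "26" = cheb == 1,
    cx_stop("connectivity must be 6, 18 or 26", "cx_validation_error"))
  g[keep, , drop = FALSE]
}

check_connectivity_pair <- function(pair) {
  ok <- list(c(6, 26), c(26, 6), c(6, 18), c(18, 6))
  if (!is.numeric(pair) || length(pair) != 2L ||
      !any(vapply(ok, function(p) all(p == pair), logical(1))))
    cx_stop("connectivity pair must be one of (6,26), (26,6), (6,18), (18,6)",
            "cx_validation_error")
  as.integer(pair)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
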