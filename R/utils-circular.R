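# Circular-coordinate helpers. Positions are 1-based; all arithmetic wraps
# modulo the genome length L.

wrapPos <- function(pos, L) ((pos - 1L) %% L) + 1L

# minimal circular distance between positions a and b
circDist <- function(a, b, L, circular = TRUE) {
  d <- abs(a - b)
  if (circular) pmin(d, L - d) else d
}

# signed difference a - b mapped into (-L/2, L/2]
circSignedDiff <- function(a, b, L, circular = TRUE) {
  if (!circular) return(a - b)
  d <- (a - b) %% L
  ifelse(d > L / 2, d - L, d)
}

# substring of a circular sequence; start 1-based, may run past the end
subseqCircular <- function(seqchar, start, width, L = nchar(seqchar),
                           circular = TRUE) {
  start <- wrapPos(start, L)
  end <- start + width - 1L
  if (end <= L) return(substr(seqchar, start, end))
  if (!circular)
    stop("window [", start, ", ", end, "] exceeds a linear sequence of ",
         L, " bp")
  paste0(substr(seqchar, start, L), substr(seqchar, 1L, end - L))
}

# overwrite a (possibly wrapping) window of a circular sequence
replaceCircular <- function(seqchar, start, replacement,
                            L = nchar(seqchar), circular = TRUE) {
  w <- nchar(replacement)
  start <- wrapPos(start, L)
  end <- start + w - 1L
  if (end <= L) {
    substr(seqchar, start, end) <- replacement
    return(seqchar)
  }
  if (!circular)
    stop("replacement window exceeds a linear sequence")
  head_len <- L - start + 1L
  substr(seqchar, start, L) <- substr(replacement, 1L, head_len)
  substr(seqchar, 1L, w - head_len) <- substr(replacement, head_len + 1L, w)
  seqchar
}
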