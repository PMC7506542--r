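# Independent brute-force oracle for transfer entropy: computes
# TE = I(X_past ; Y_future | Y_past) from plain joint entropies
# (H(X,Yp) + H(Yp,Yf) - H(Yp) - H(X,Yp,Yf)), each obtained by direct
# tabulation -- a different decomposition and code path than the
# implementation's conditional-probability sum.
te_oracle <- function(x, y) {
  n <- length(x)
  xp <- x[-n]; yp <- y[-n]; yf <- y[-1]
  H <- function(...) {
    counts <- table(paste(...))
    p <- as.numeric(counts) / sum(counts)
    -sum(p * log2(p))
  }
  H(xp, yp) + H(yp, yf) - H(yp) - H(xp, yp, yf)
}

# enumerate the i-th of 2^len binary sequences
int_to_bits <- function(i, len) as.integer(intToBits(i))[seq_len(len)]

# a quick small baseline network used by several simulator tests
tiny_network <- function(scale = 0.1, wiring_seed = 1) {
  build_network(default_params(), scale = scale, wiring_seed = wiring_seed)
}
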