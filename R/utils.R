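# internal helpers shared across modules

.centerCols <- function(x) sweep(x, 2, colMeans(x), "-")

.momentSkewness <- function(x) {
  x <- x - mean(x)
  mean(x^3) / (mean(x^2)^1.5)
}

.momentKurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / (mean(x^2)^2)
}

# linear detrend each column against the frame index
.detrendCols <- function(x) {
  tn <- nrow(x)
  tt <- cbind(1, seq_len(tn))
  x - tt %*% qr.coef(qr(tt), x)
}

.stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
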