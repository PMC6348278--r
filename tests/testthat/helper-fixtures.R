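# Hand-built trials with exactly known geometry, for tests whose expected
# values are computed by hand or by an independent oracle.

# A trial of `segment_sizes` segments separated by gaps of `gap_s` seconds;
# stride times and lengths constant unless vectors are supplied.
make_toy_trial <- function(segment_sizes, gap_s = 3,
                           stride_time = 1, stride_length = 100,
                           subject_id = "toy", group = "HE",
                           protocol = NULL) {
  n <- sum(segment_sizes)
  times <- rep_len(stride_time, n)
  lengths <- rep_len(stride_length, n)
  gaps <- rep_len(gap_s, max(length(segment_sizes) - 1, 0))
  onset <- cumsum(c(0, times[-n]))
  if (length(segment_sizes) > 1) {
    seg_of <- rep(seq_along(segment_sizes), segment_sizes)
    onset <- onset + c(0, cumsum(gaps))[seg_of]
  }
  protocol <- protocol %||% protocol_spec(10, length(segment_sizes))
  gait_trial(
    tibble::tibble(
      stride_index = seq_len(n) - 1L,
      onset_s = onset,
      stride_length_pct_stature = lengths,
      stride_time_s = times
    ),
    subject_id = subject_id, group = group, protocol = protocol
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent ICC(2,1) oracle: mean squares taken from a two-way aov() fit,
# never from the package's own sums of squares.
icc21_oracle <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  d <- data.frame(
    y = as.vector(mat),
    subj = factor(rep(seq_len(n), times = k)),
    seg = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subj + seg, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
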