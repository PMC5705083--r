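# Small shared fixtures built in code.

three_point_d <- function() {
  distance_matrix(
    matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
      dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
    )
  )
}
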