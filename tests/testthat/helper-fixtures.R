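## shared fixtures: built once per test run
tiny <- makeFixture("tiny_chain")
base <- makeFixture("baseline")

## closed-form steady state of the tiny chain
tinyClosedForm <- function(params) {
  k <- getConstants(params)
  c(A = k[["k_in"]] / k[["k_ab"]],
    B = k[["k_in"]] / k[["k_bc"]],
    C = k[["k_in"]] / k[["k_out"]])
}

relErr <- function(x, y) abs(x - y) / abs(y)
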