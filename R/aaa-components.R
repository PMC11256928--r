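# Component naming shared across the package: C is the correct match, J1/J2
# the top and runner-up partially incorrect matches, I1/I2 the top and
# runner-up incorrect matches. The top score mixes C, J1, I1; the second
# score mixes all five.
TOP_COMPONENTS <- c("C", "J1", "I1")
ALL_COMPONENTS <- c("C", "J1", "J2", "I1", "I2")

# Dominance chain enforced on the five-component model (and its one-sample
# restriction): each pair (upper, lower).
CHAIN_TWO_SAMPLE <- list(c("C", "J1"), c("J1", "J2"),
                         c("J2", "I1"), c("I1", "I2"))
CHAIN_ONE_SAMPLE <- list(c("C", "J1"), c("J1", "I1"))
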