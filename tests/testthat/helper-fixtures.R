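# tiny hand-built models used across test files

# EX_A -> T_A -> R_AB -> bio, single carbon source, all irreversible
linear_model <- function() {
  mets <- data.frame(id = c("A_e", "A_c", "B_c"),
                     name = c("A_e", "A_c", "B_c"),
                     compartment = c("e", "c", "c"),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_A_e", "T_A", "R_AB", "bio"),
                     lower_bound = c(-100, 0, 0, 0),
                     upper_bound = c(100, 100, 100, 100),
                     gpr = c("", "g_t", "g_ab", ""),
                     stringsAsFactors = FALSE)
  st <- list(EX_A_e = c(A_e = -1), T_A = c(A_e = -1, A_c = 1),
             R_AB = c(A_c = -1, B_c = 1), bio = c(B_c = -1))
  new_model("linear", mets, rxns, st, "bio")
}

media_A <- function(uptake = 10) new_media("mA", c(A_e = uptake))

# linear model plus a dead-end branch reaction (C_c has no consumer)
deadend_model <- function() {
  m <- linear_model()
  add_reaction(m, "R_dead", c(A_c = -1, C_c = 1), 0, 100, gpr = "g_dead")
}
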