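# block array: nz focal units followed by ny of the other type
block_array <- function(nz, ny, labels = c("Z", "Y")) {
  repeat_array(rep(labels, c(nz, ny)))
}

# random two-type array of given length
random_array <- function(len, p_z = 0.5) {
  repeat_array(sample(c("Z", "Y"), len, replace = TRUE,
                      prob = c(p_z, 1 - p_z)))
}

# counts of Z and Y regardless of presence
zy_counts <- function(units) {
  u <- as.character(units)
  c(Z = sum(u == "Z"), Y = sum(u == "Y"))
}
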