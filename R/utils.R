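# Internal helpers shared across modules.

# Standard 20-letter amino-acid alphabet.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Conserved histidine-kinase domains: HATPase_c and HisKA.
HK_CONSERVED_ACCS <- c("PF02518", "PF00512")

random_aa_string <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# Substitute up to floor(rate * len) positions, so identity to the template
# never drops below 1 - rate. The replacement letter always differs from the
# original.
mutate_sequence <- function(seq, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  max_mut <- floor(rate * length(chars))
  if (max_mut == 0) return(seq)
  n_mut <- sample.int(max_mut + 1L, 1L) - 1L
  if (n_mut == 0) return(seq)
  pos <- sample.int(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Deterministic sub-seed derivation: keeps derived seeds valid 32-bit ints.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# C-locale, radix-based order: stable across platforms and locales.
stable_order <- function(...) order(..., method = "radix")
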