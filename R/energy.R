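# Nucleotide codes, base-pair table and nearest-neighbor stacking energies.
#
# The energy model is intentionally minimal: Watson-Crick and G.U wobble
# pairs, Turner-style helix stacking free energies (kcal/mol, 37C), no
# dangles, no loop or multiloop penalties.  The free energy of a structure
# is the sum of stacking terms over directly adjacent pairs (i,j)/(i+1,j-1).

# base codes: A=1, C=2, G=3, U/T=4
.BASE_CHARS <- c("A", "C", "G", "U")

# pair indices: 1=AU 2=UA 3=CG 4=GC 5=GU 6=UG, 0 = not pairable
.PAIR_INDEX <- matrix(0L, 4, 4)
.PAIR_INDEX[1, 4] <- 1L
.PAIR_INDEX[4, 1] <- 2L
.PAIR_INDEX[2, 3] <- 3L
.PAIR_INDEX[3, 2] <- 4L
.PAIR_INDEX[3, 4] <- 5L
.PAIR_INDEX[4, 3] <- 6L

# stack table S[p1, p2]: pair p1 = (i,j), pair p2 = (i+1,j-1), 5'->3' on the
# top strand.  Values follow the classic Turner nearest-neighbor set.
.STACK_ENERGY <- matrix(c(
  # p2:   AU     UA     CG     GC     GU     UG      p1:
  -0.93, -1.10, -2.24, -2.08, -0.55, -1.36,  # AU
  -1.33, -0.93, -2.35, -2.11, -1.00, -0.99,  # UA
  -2.11, -2.08, -3.26, -2.36, -1.41, -2.11,  # CG
  -2.35, -2.24, -3.42, -3.26, -1.53, -2.51,  # GC
  -0.99, -1.36, -2.51, -2.11, -0.50,  1.29,  # GU
  -1.00, -0.55, -1.53, -1.41,  0.30, -0.50   # UG
), nrow = 6, byrow = TRUE)

# Convert a nucleotide string to integer codes; T and U are equivalent.
seq_to_codes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- utf8ToInt(chartr("ACGUTacgut", "1234412344", seq)) - 48L
  if (length(x) && (any(x < 1L) || any(x > 4L))) {
    bad <- which(x < 1L | x > 4L)[1L]
    stop("non-nucleotide character at position ", bad, " in sequence")
  }
  x
}

codes_to_seq <- function(codes, rna = FALSE) {
  chars <- if (rna) c("A", "C", "G", "U") else c("A", "C", "G", "T")
  paste(chars[codes], collapse = "")
}

#' Reverse complement of DNA/RNA strings
#'
#' @param x character vector of nucleotide strings (A/C/G/T/U/N).
#' @return character vector of reverse complements (DNA alphabet).
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUNacgtun", "TGCAANTGCAAN", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}

.pair_index <- function(a, b) .PAIR_INDEX[cbind(a, b)]

.stack_energy <- function(p1, p2) .STACK_ENERGY[cbind(p1, p2)]
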