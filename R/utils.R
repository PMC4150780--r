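# shared helpers (internal)

PAIR_CODES <- c("AU", "UA", "CG", "GC", "GU", "UG")
BASES <- c("A", "C", "G", "U")

# encode an RNA string as integer codes A=0 C=1 G=2 U=3; error otherwise
encodeRna <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  code <- match(ch, BASES) - 1L
  if (anyNA(code)) {
    bad <- unique(ch[is.na(code)])
    stop("invalid RNA alphabet character(s): ", paste(bad, collapse = ", "))
  }
  code
}

decodeRna <- function(code) paste(BASES[code + 1L], collapse = "")

# DNA/RNA normalization: uppercase, T -> U; reject anything outside A,C,G,T,U,N
normalizeSeq <- function(x, allow_n = FALSE) {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  ok <- if (allow_n) "ACGUN" else "ACGU"
  ch <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  bad <- setdiff(ch, strsplit(ok, "", fixed = TRUE)[[1]])
  if (length(bad))
    stop("sequence contains disallowed alphabet character(s): ",
         paste(bad, collapse = ", "))
  x
}

rnaComplement <- function(x) chartr("ACGU", "UGCA", toupper(x))

rnaRevComp <- function(x) {
  paste(rev(strsplit(rnaComplement(x), "", fixed = TRUE)[[1]]), collapse = "")
}

isWatsonCrick <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
  (a == "C" & b == "G") | (a == "G" & b == "C")
}

# 0-based half-open interval helpers
intervalsOverlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# substring by 0-based half-open interval
substr0 <- function(x, start, end) substr(x, start + 1L, end)

# round half up to `digits` decimals (summary reporting convention)
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string")
}
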