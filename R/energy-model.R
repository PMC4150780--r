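#' @include AllClasses.R
NULL

#' Read a nearest-neighbor energy parameter file
#'
#' Parses the versioned TSV parameter format shipped with the package:
#' rows of \code{category / key / size / value} covering the stack table
#' (keys like \code{"CG:GC"}), the hairpin/bulge/internal loop size tables,
#' and scalar constants.
#'
#' @param path path to a parameter TSV.
#' @return an \linkS4class{EnergyModel}.
#' @seealso [defaultEnergyModel()]
#' @export
readEnergyModel <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  st <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_CODES, PAIR_CODES))
  srows <- tab[tab$category == "stack", ]
  for (k in seq_len(nrow(srows))) {
    pp <- strsplit(srows$key[k], ":", fixed = TRUE)[[1]]
    st[pp[1], pp[2]] <- srows$value[k]
  }
  if (anyNA(st)) stop("stack table incomplete in ", path)
  loop <- function(cat) {
    r <- tab[tab$category == cat, ]
    v <- rep(NA_real_, max(r$size))
    v[r$size] <- r$value
    v
  }
  consts <- tab[tab$category == "const", ]
  cv <- setNames(consts$value, consts$key)
  new("EnergyModel",
      stack = st,
      hairpin = loop("hairpin"),
      bulge = loop("bulge"),
      internal = loop("internal"),
      loop_extrap = cv[["loop_extrap"]],
      terminal_au = cv[["terminal_au"]],
      duplex_init = cv[["duplex_init"]],
      ml_init = cv[["ml_init"]],
      ml_branch = cv[["ml_branch"]],
      ml_unpaired = cv[["ml_unpaired"]],
      temperature = cv[["temperature"]],
      RT = cv[["RT"]],
      min_hairpin = as.integer(cv[["min_hairpin"]]),
      max_loop_side = as.integer(cv[["max_loop_side"]]))
}

#' Default pinned energy model
#'
#' Loads the Turner-style parameter set shipped with the package
#' (\code{energy_params_v1.tsv}): 37 C, RT = 0.6163 kcal/mol, minimal
#' hairpin 3 nt, bulge/internal loops up to 15 nt per side.
#'
#' @return an \linkS4class{EnergyModel}.
#' @examples
#' model <- defaultEnergyModel()
#' model
#' @export
defaultEnergyModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "energy_params_v1.tsv",
                          package = "mirvar", mustWork = TRUE)
      cache <<- readEnergyModel(path)
    }
    cache
  }
})

# flatten for the C++ layer
modelToList <- function(model) {
  list(stack = model@stack,
       hairpin = model@hairpin,
       bulge = model@bulge,
       internal = model@internal,
       loop_extrap = model@loop_extrap,
       terminal_au = model@terminal_au,
       duplex_init = model@duplex_init,
       ml_init = model@ml_init,
       ml_branch = model@ml_branch,
       ml_unpaired = model@ml_unpaired,
       RT = model@RT,
       min_hairpin = model@min_hairpin,
       max_loop_side = model@max_loop_side)
}
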