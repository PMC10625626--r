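#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr imap
NULL

# single place for the physical constants the ruler needs
.AVOGADRO <- 6.02214076e23

# default cellular DNA mass: diploid mouse genome, 2 x 2.73e9 bp x 650 g/mol/bp / N_A
.DEFAULT_DNA_PG <- 5.89e-12

`%not_in%` <- function(x, table) !(x %in% table)

# stop with a classed condition so tests can target errors precisely
stop_cd8 <- function(msg, class) {
  rlang::abort(msg, class = paste0("cd8omics_", class))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop_cd8(sprintf("`%s` must be a single number in (0, 1), got %s",
                     name, paste(format(x), collapse = ", ")), "bad_argument")
  }
  invisible(x)
}
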