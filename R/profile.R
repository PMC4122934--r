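# The consensus cluster model: family inventory with copy-number ranges,
# the conserved baseplate gene order, and the consensus cluster size.

#' The consensus PLTS family profile
#'
#' Encodes the minimal consensus component inventory of the phage-tail
#' derived cluster: the structural families with their observed per-cluster
#' copy-number ranges, the conserved baseplate gene order
#' (LysM, VgrG, PAAR, Gp25, BaseplateJ, P2I), and the consensus cluster
#' size of 13-16 genes.  `VgrG_GPD`/`VgrG_baseV` name the split variant of
#' the baseplate hub/spike gene seen in several lineages.
#'
#' @param families Optional replacement tibble with columns `family`,
#'   `copy_min`, `copy_max`, `core`.
#' @param baseplate_order Conserved baseplate family order (5' to 3').
#' @param consensus_size_range Length-2 integer vector.
#' @return An object of class `plts_profile`.
#' @export
plts_profile <- function(families = NULL,
                         baseplate_order = c("LysM", "VgrG", "PAAR", "Gp25",
                                             "BaseplateJ", "P2I"),
                         consensus_size_range = c(13L, 16L)) {
  if (is.null(families)) {
    families <- tibble(
      family = c("VgrG", "LysM", "PAAR", "BaseplateJ", "Gp25", "P2I",
                 "Gp19", "Sheath", "Gp3like", "AAA_ATPase",
                 "VgrG_GPD", "VgrG_baseV"),
      copy_min = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L),
      copy_max = c(1L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 1L, 1L, 1L),
      core = TRUE)
  }
  families <- as_tibble(families)
  stopifnot(all(c("family", "copy_min", "copy_max", "core") %in%
                  names(families)))
  if (any(families$copy_min > families$copy_max)) {
    abort("copy_min must not exceed copy_max")
  }
  if (!all(baseplate_order %in% families$family)) {
    abort("baseplate_order must be a subset of the profile families")
  }
  if (!any(families$core)) abort("at least one family must be core")
  structure(list(families = families,
                 baseplate_order = baseplate_order,
                 consensus_size_range = as.integer(consensus_size_range)),
            class = "plts_profile")
}

core_families <- function(profile) {
  profile$families$family[profile$families$core]
}

#' @export
print.plts_profile <- function(x, ...) {
  cat(sprintf("<plts_profile> %d families (%d core); baseplate order: %s\n",
              nrow(x$families), sum(x$families$core),
              paste(x$baseplate_order, collapse = " > ")))
  invisible(x)
}
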