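#' Packaged replicate-study fixtures
#'
#' Two published replicate-ensemble FEP studies ship with the package as
#' plain-text fixtures: four ligand transformations of the human bromodomain
#' BRD4 and six transformations of the Leu99Ala T4 lysozyme mutant, each with
#' five velocity-induced (VIS) and five solvent-induced (SIS) independent
#' replicates per transformation, the per-replicate MBAR sigmas, the
#' experimental reference affinities, and the thermodynamic cycle each ligand
#' set supports. The lysozyme Ben->Phe experimental value is a lower bound
#' and is flagged as such.
#'
#' @param study `"brd4"` or `"lysozyme"`.
#' @return List with `replicates` (replicate table), `experimental`
#'   (reference table) and `cycles` (list of [cycle_definition()]).
#' @examples
#' fx <- fep_fixture("brd4")
#' nrow(fx$replicates)  # 4 transformations x 2 conditions x 5 replicates
#' @export
fep_fixture <- function(study = c("brd4", "lysozyme")) {
  study <- match.arg(study)
  path <- function(f) system.file("extdata", f, package = "fepens",
                                  mustWork = TRUE)
  list(
    replicates = read_replicates(path(paste0(study, "_replicates.csv"))),
    experimental = read_experimental(path(paste0(study, "_experimental.csv"))),
    cycles = read_cycles(path(paste0(study, "_cycles.json")))
  )
}
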