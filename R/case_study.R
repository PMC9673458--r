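#' The 13-node rural-health case study
#'
#' Loads the packaged case study on the health determinants of rural older
#' adults in China: 12 factor nodes in four first-level groups — lifestyle
#' (C1 balanced diet, C2 quality of sleep, C3 physical exercise, C4
#' unhealthy lifestyle, C5 mentality), health management (C6 preventive
#' medical service utilization, C7 chronic diseases management),
#' socio-economic status (C8 income, C9 occupation, C10 education), living
#' environment (C11 environmental pollution, C12 intergenerational
#' relationship) — plus the outcome node R (self-rated health). Initial
#' states are PLTSs over the terms \eqn{\{s_{-3}, s_0, s_3\}} of the 11-term
#' state scale, derived from national survey proportions (CLHLS, CHARLS,
#' CGSS).
#'
#' The fixture ships the node states only. The expert-elicited connection
#' matrix is not redistributable with the package; transcribe it into the
#' [read_connection_matrix()] dialect (see [write_matrix_template()]) and
#' attach it with [attach_matrix()]. For demonstrations and tests the
#' package includes a clearly-labelled synthetic stand-in matrix
#' (`synthetic_connection_matrix.csv`) whose sign structure follows the
#' published causal diagram but whose strengths are invented.
#'
#' @param matrix optional connection matrix (path or data frame) to attach.
#' @return A [plfcm_model()].
#' @examples
#' m <- load_case_study()
#' plts_score(m$states[["R"]])  # 0.9
#' @export
load_case_study <- function(matrix = NULL) {
  path <- system.file("extdata", "rural_health_case_study.yaml",
                      package = "plfcm", mustWork = TRUE)
  model <- read_plfcm_model(path)
  if (!is.null(matrix)) model <- attach_matrix(model, matrix)
  model
}

#' Path to the bundled synthetic demonstration matrix
#'
#' A synthetic connection matrix for the case-study nodes: its edges follow
#' the qualitative causal structure described for the rural-health system
#' (socio-economic status driving lifestyle and environment, lifestyle
#' driving health management, everything feeding the outcome), but every
#' strength is generated, not elicited. It exists so that the full pipeline
#' can be demonstrated end to end; results computed from it are
#' illustrative only.
#'
#' @return A file path.
#' @export
synthetic_matrix_path <- function() {
  system.file("extdata", "synthetic_connection_matrix.csv",
              package = "plfcm", mustWork = TRUE)
}
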