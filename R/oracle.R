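#' Reference convex solver for the row-wise lq proximal problem
#'
#' Bridges to a general-purpose constrained solver (scipy, via the bundled
#' `inst/oracle/prox_oracle.py` script) to minimize
#' `1/2 ||theta - v||^2 + lam ||theta||_q` numerically, independently of the
#' closed forms and root-finders in [project_row_lq]. Used for verification;
#' it is orders of magnitude slower than the projection itself.
#'
#' @param cases list of cases, each a list with `v` (numeric vector), `q`
#'   (number, may be `Inf`) and `lam`.
#' @param python path to the python interpreter (default: found on PATH).
#' @return A list of numeric minimizers, one per case.
#' @export
prox_convex_oracle <- function(cases, python = Sys.which("python")) {
  if (!nzchar(python)) stop("no python interpreter found on PATH")
  script <- system.file("oracle", "prox_oracle.py", package = "mkmtl")
  if (!nzchar(script)) stop("bundled oracle script not found")
  payload <- list(cases = lapply(cases, function(cs) {
    list(v = as.numeric(cs$v),
         q = if (is.infinite(cs$q)) "inf" else cs$q,
         lam = cs$lam)
  }))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = TRUE)
  status <- system2(python, c(script, fin, fout))
  if (status != 0L || !file.exists(fout)) {
    stop("convex oracle failed with status ", status)
  }
  out <- jsonlite::fromJSON(fout, simplifyVector = FALSE)
  lapply(out$solutions, function(s) as.numeric(unlist(s)))
}
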