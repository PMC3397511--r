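# Bridge to the bundled RDKit helper. All chemistry the package cannot do in
# native R (SMILES parsing, conformer embedding, Gasteiger charges, SMARTS
# matching, MOL2 input) goes through one python subprocess per request.

#' Is the RDKit chemistry bridge available?
#'
#' The package delegates SMILES/MOL2 input, charge assignment and substructure
#' matching to RDKit through the `python` interpreter on the PATH. Pure-numeric
#' functionality (fields, PLS, validation, contours, synthetic benchmark) does
#' not need it.
#'
#' @return `TRUE` if `python` can import RDKit.
#' @export
rdkit_available <- function() {
  python <- Sys.which("python")
  if (!nzchar(python)) return(FALSE)
  status <- suppressWarnings(system2(python, c("-c", shQuote("import rdkit")),
                                     stdout = FALSE, stderr = FALSE))
  identical(status, 0L)
}

chem_bridge <- function(request) {
  python <- Sys.which("python")
  if (!nzchar(python)) stop("no `python` interpreter on the PATH")
  script <- system.file("python", "chem_bridge.py", package = "qsar3d")
  if (!nzchar(script)) stop("bundled chem_bridge.py not found")
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  jsonlite::write_json(request, infile, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(system2(python, shQuote(script), stdout = TRUE,
                                  stdin = infile, stderr = FALSE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L || length(out) == 0L)
    stop("chemistry bridge failed (python exit status ", status, ")")
  res <- jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = FALSE)
  if (!isTRUE(res$ok)) stop("chemistry bridge: ", res$error)
  res
}

bridge_molecules <- function(res) {
  lapply(res$molecules, function(m) {
    atoms <- data.frame(
      element = vapply(m$atoms, function(a) a$element, character(1)),
      x = vapply(m$atoms, function(a) a$xyz[[1]], numeric(1)),
      y = vapply(m$atoms, function(a) a$xyz[[2]], numeric(1)),
      z = vapply(m$atoms, function(a) a$xyz[[3]], numeric(1)),
      charge = vapply(m$atoms, function(a) a$charge, numeric(1)),
      fcharge = vapply(m$atoms, function(a) as.integer(a$fcharge %||% 0L),
                       integer(1)),
      stringsAsFactors = FALSE
    )
    bonds <- if (length(m$bonds)) {
      data.frame(
        from  = vapply(m$bonds, function(b) b[[1]], numeric(1)) + 1L,
        to    = vapply(m$bonds, function(b) b[[2]], numeric(1)) + 1L,
        order = vapply(m$bonds, function(b) b[[3]], numeric(1))
      )
    } else {
      data.frame(from = integer(), to = integer(), order = numeric())
    }
    molecule(id = m$id %||% NA_character_, atoms = atoms, bonds = bonds,
             formal_charge = m$formal_charge %||% 0)
  })
}
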