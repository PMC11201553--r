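#' Elements covered by the ANI-2x potential
#'
#' ANI-2x is trained on organic molecules built from these seven elements;
#' structures containing anything else (e.g. Br) cannot be evaluated and
#' are rejected before any model call.
#' @format character vector of element symbols.
#' @export
ani2x_elements <- c("H", "C", "N", "O", "S", "F", "Cl")

#' Is the ANI-2x backend available?
#'
#' The adapter drives the published torchani implementation through the
#' `python` interpreter on the PATH; this checks whether the `torchani`
#' module can be imported.
#' @param python path to the python interpreter.
#' @return logical.
#' @export
ani2x_available <- function(python = Sys.which("python")) {
  if (!nzchar(python)) return(FALSE)
  status <- suppressWarnings(system2(python,
                                     c("-c", shQuote("import torchani")),
                                     stdout = FALSE, stderr = FALSE))
  identical(status, 0L)
}

#' ANI-2x potential backend
#'
#' Wraps the ANI-2x neural-network potential (torchani) as an
#' [energy_model()]. ANI-2x emulates the wB97X/6-31G(d) level of theory
#' for molecules made of H, C, N, O, S, F and Cl; Hartree energies and
#' Hartree/Bohr forces from the model are converted to kcal/mol and
#' kcal/mol/A. Evaluation is deterministic for fixed coordinates.
#'
#' The adapter is optional: the rest of the package (optimizer, refinement
#' protocol, metrics) is exercised end-to-end on analytic potentials and
#' does not need it.
#'
#' @param elements character vector giving the element of each atom, in
#'   atom order; every evaluation uses this assignment.
#' @param python path to a python interpreter with torchani installed.
#' @return an [energy_model()] with `supported_elements` set to
#'   [ani2x_elements].
#' @export
ani2x_adapter <- function(elements, python = Sys.which("python")) {
  elements <- toupper(elements)
  bad <- setdiff(unique(elements), toupper(ani2x_elements))
  if (length(bad))
    stop("element(s) not supported by the ANI-2x potential: ",
         paste(bad, collapse = ", "),
         " (ANI-2x covers H, C, N, O, S, F, Cl only)")
  if (!ani2x_available(python))
    stop("the ANI-2x backend is unavailable: the 'torchani' Python package ",
         "could not be imported. Install it with 'pip install torchani' ",
         "and ensure 'python' is on the PATH.")
  symbols <- pdb_element_case(elements)
  eval_fn <- function(coords) {
    inp <- tempfile(fileext = ".json")
    outp <- tempfile(fileext = ".json")
    on.exit(unlink(c(inp, outp)), add = TRUE)
    writeLines(c(
      paste0("[[", paste(sprintf('"%s"', symbols), collapse = ","), "],"),
      paste0("[", paste(apply(coords, 1, function(r)
        sprintf("[%.12g,%.12g,%.12g]", r[1], r[2], r[3])), collapse = ","),
        "]]")), inp)
    script <- sprintf(
      "import json,sys,torch,torchani\nsym,xyz=json.load(open('%s'))\nm=torchani.models.ANI2x(periodic_table_index=False)\nsp=m.species_to_tensor(''.join(sym)).unsqueeze(0)\nc=torch.tensor([xyz],dtype=torch.float64,requires_grad=True)\ne=m((sp,c)).energies\nf=-torch.autograd.grad(e.sum(),c)[0]\njson.dump({'energy':e.item(),'forces':f.squeeze(0).tolist()},open('%s','w'))",
      inp, outp)
    status <- system2(python, c("-c", shQuote(script)),
                      stdout = FALSE, stderr = FALSE)
    if (!identical(status, 0L) || !file.exists(outp))
      stop("ANI-2x evaluation failed (torchani call returned an error)")
    res <- parse_ani_json(readLines(outp, warn = FALSE))
    # torchani reports Hartree and Hartree/A (cartesian gradient in A)
    list(energy = res$energy * phys_constants$hartree_to_kcalmol,
         forces = res$forces * phys_constants$hartree_to_kcalmol)
  }
  energy_model(eval_fn, toupper(ani2x_elements), "ani2x")
}

# minimal parser for the adapter's fixed {'energy': x, 'forces': [[..]]} blob
parse_ani_json <- function(txt) {
  txt <- paste(txt, collapse = "")
  en <- as.numeric(sub('.*"energy":\\s*([-0-9.eE+]+).*', "\\1", txt))
  fs <- sub('.*"forces":\\s*\\[(.*)\\]\\s*}\\s*$', "\\1", txt)
  rows <- strsplit(gsub("\\],\\s*\\[", ";", gsub("[][]", "", fs)), ";")[[1]]
  forces <- t(vapply(strsplit(rows, ","),
                     function(r) as.numeric(r), numeric(3)))
  list(energy = en, forces = forces)
}

#' Select an energy backend by name
#'
#' @param name one of `"lj"`, `"harmonic"`, `"ani2x"`.
#' @param ... passed to the backend constructor ([lj_pair_model()],
#'   [harmonic_well_model()] or [ani2x_adapter()]).
#' @return an [energy_model()].
#' @export
potential_backend <- function(name = c("lj", "harmonic", "ani2x"), ...) {
  name <- match.arg(name)
  switch(name,
         lj = lj_pair_model(...),
         harmonic = harmonic_well_model(...),
         ani2x = ani2x_adapter(...))
}
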