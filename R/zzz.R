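# Point reticulate at the python on PATH (which provides scipy/HiGHS)
# unless the user has configured an interpreter already.
.onLoad <- function(libname, pkgname) {
  if (Sys.getenv("RETICULATE_PYTHON") == "" &&
      is.null(getOption("reticulate.python"))) {
    py <- Sys.which("python3")
    if (py == "") py <- Sys.which("python")
    if (py != "") Sys.setenv(RETICULATE_PYTHON = py)
  }
}
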