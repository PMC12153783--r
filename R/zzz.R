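.onLoad <- function(libname, pkgname) {
  thi_register("silva", function(tair, ws)
    6.3952 + 0.08964 * tair + 0.01018 * ws^2)
}
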