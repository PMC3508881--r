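# re-exported operators

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
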