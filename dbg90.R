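library(emwtrials)
# does RA at 85% IKr block develop only after long drug exposure?
c0 <- simulate_paced(protocol = stimulus_protocol(beats = 500))
st <- c0$final_state
for (chunk in 1:10) {
  tr <- simulate_paced(blocks = block_fractions(IKr = 0.85),
                       protocol = stimulus_protocol(beats = 50), init = st)
  st <- tr$final_state
  dv <- diff(tr$v)/diff(tr$time); sel <- tr$time[-1] > 100 & tr$time[-1] < 950
  cat(sprintf("beat %3d: v1=%.0f APD90=%.0f maxlate=%.4f vend=%.0f CaMKt=%.4f\n",
      chunk*50, tr$v[1], ifelse(is.na(ap_biomarkers(tr)$APD90), NaN, ap_biomarkers(tr)$APD90),
      max(dv[sel]), tail(tr$v,1), st[["CaMKt"]]))
}
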