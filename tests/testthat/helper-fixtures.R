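# Shared study-condition fixtures: low-growth chemostat parameter set,
# retentostat-fitted parameter set, and the default two-vessel reactor.

chemo_params <- function() pirt_params(m_S = 0.00437, Y_XS_max = 0.544)
reten_params <- function() pirt_params(m_S = 0.0037, Y_XS_max = 0.544)
default_cfg <- function() reactor_config()

# Constant-feed configuration for steady-state fixed-point checks.
constant_feed_cfg <- function(cs = 3.5) {
  reactor_config(C_S_high = cs, C_S_low = cs)
}
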