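# Operational kinase hallmark motifs used by the identification funnel.
# These are configuration, not transcriptions of official database entries:
# the "protein kinase domain" hallmark in particular stands in for what a
# profile scanner would report, expressed here as a catalytic-loop pattern
# so that the packaged PROSITE-style matcher can evaluate it. Substitute
# your own file to change the hallmark set.
patterns:
  - name: atp_binding
    description: glycine-rich ATP-binding loop with the invariant lysine
    pattern: "G-x-G-x(2)-G-x-V-[KR]"
  - name: st_active_site
    description: serine/threonine kinase catalytic (HRD) active-site loop
    pattern: "[LIVM]-x-H-[RK]-D-[LIVM]-K-x(2)-N"
  - name: kinase_domain
    description: activation-segment DFG motif marking the kinase domain
    pattern: "D-F-G-x(2)-[LIVM]"
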