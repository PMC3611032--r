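<?xml version="1.0" encoding="UTF-8"?>
<panel dialect="ahpdx-panel-1" id="P001-2013-02-15" patient="P001" collected="2013-02-15">
  <analyte name="HDL" value="45" units="mg/dL"/>
  <analyte name="LDL" value="70" units="mg/dL"/>
  <analyte name="Triglyceridea" value="120" units="mg/dL"/>
  <notes>Routine lipid panel; fasting sample.</notes>
</panel>
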