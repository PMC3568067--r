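<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="mini">
    <listOfCompartments><compartment id="cyto"/><compartment id="ext"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="cyto" boundaryCondition="false"/>
      <species id="B" compartment="cyto"/>
      <species id="X" compartment="ext" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="r1" reversible="false">
        <listOfReactants><speciesReference species="X"/></listOfReactants>
        <listOfProducts><speciesReference species="A"/></listOfProducts>
        <kineticLaw><listOfParameters><parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="10"/></listOfParameters></kineticLaw>
      </reaction>
      <reaction id="r2" reversible="true">
        <listOfReactants><speciesReference species="A"/></listOfReactants>
        <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
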