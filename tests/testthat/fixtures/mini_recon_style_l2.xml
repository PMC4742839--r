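<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic miniature in the style of the classic Recon 1 Level 2 SBML
     distribution (kinetic-law bounds, GENE_ASSOCIATION / SUBSYSTEM notes,
     boundary "_b" species). Hand-written test fixture, not a real model. -->
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
  <model id="mini_recon_style" name="synthetic excerpt">
    <listOfCompartments>
      <compartment id="e"/>
      <compartment id="c"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_glc_b" name="glucose boundary" compartment="e" boundaryCondition="true"/>
      <species id="M_glc_e" name="glucose (extracellular)" compartment="e"/>
      <species id="M_glc_c" name="glucose (cytosol)" compartment="c"/>
      <species id="M_g6p_c" name="glucose 6-phosphate" compartment="c"/>
      <species id="M_h_c" name="proton" compartment="c"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_EX_glc" name="glucose exchange" reversible="true">
        <listOfReactants>
          <speciesReference species="M_glc_e"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_glc_b"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-5"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_GLCt1" name="glucose transport" reversible="true">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: HGNC_11005</p>
            <p>SUBSYSTEM: Transport, Extracellular</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="M_glc_e"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_glc_c"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-1000"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_HEX1" name="hexokinase" reversible="false">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: (HGNC_4195 or HGNC_4922)</p>
            <p>SUBSYSTEM: Glycolysis</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="M_glc_c"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_g6p_c"/>
          <speciesReference species="M_h_c"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_DM_g6p" name="g6p sink" reversible="false">
        <listOfReactants>
          <speciesReference species="M_g6p_c"/>
        </listOfReactants>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
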