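# colvars bias protocol: pou_hd_insertion

colvar {
    name cv_steer_pouhd_inner
    distanceInv {
        exponent 100
        group1 { roles=TF subdomain=POU_HD atoms=CA }
        group2 { roles=DNA region=inner_gyre atoms=P }
    }
}
harmonic {
    name steer_pouhd_inner
    colvars { cv_steer_pouhd_inner }
    forceConstant 10
    centers 5
    targetCenters 15
    targetTime 250
}

colvar {
    name cv_steer_pouhd_outer
    distanceInv {
        exponent 100
        group1 { roles=TF subdomain=POU_HD atoms=CA }
        group2 { roles=DNA region=outer_gyre_3p atoms=P }
    }
}
harmonic {
    name steer_pouhd_outer
    colvars { cv_steer_pouhd_outer }
    forceConstant 10
    centers 32
    targetCenters 12
    targetTime 250
}

colvar {
    name cv_steer_pouhd_l3
    distanceInv {
        exponent 100
        group1 { roles=TF subdomain=POU_HD atoms=CA }
        group2 { roles=DNA region=linker_3p atoms=P }
    }
}
harmonic {
    name steer_pouhd_l3
    colvars { cv_steer_pouhd_l3 }
    forceConstant 10
    centers 58
    targetCenters 28
    targetTime 250
}

colvar {
    name cv_wall_dmin_tails_outer
    distanceInv {
        exponent 100
        group1 { roles=H3-A+H2A-A segment=tail atoms=CA }
        group2 { roles=DNA region=outer_gyre_3p atoms=P }
    }
}
harmonicWalls {
    name wall_dmin_tails_outer
    colvars { cv_wall_dmin_tails_outer }
    forceConstant 10
    lowerWalls 30
}

colvar {
    name cv_wall_coord_tails_outer
    coordNum {
        cutoff 4
        expNumer 6
        expDenom 12
        group1 { roles=H3-A+H2A-A segment=tail atoms=CA }
        group2 { roles=DNA region=outer_gyre_3p atoms=P }
    }
}
harmonicWalls {
    name wall_coord_tails_outer
    colvars { cv_wall_coord_tails_outer }
    forceConstant 10
    upperWalls 0
}

colvar {
    name cv_wall_dmin_intergyre
    distanceInv {
        exponent 100
        group1 { roles=DNA region=inner_gyre atoms=P }
        group2 { roles=DNA region=outer_gyres atoms=P }
    }
}
harmonicWalls {
    name wall_dmin_intergyre
    colvars { cv_wall_dmin_intergyre }
    forceConstant 10
    lowerWalls 20
}
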